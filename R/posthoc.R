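## Post-hoc analyses: cell-specific rates, transcript/enzyme/capacity vs.
## rate relations and their hysteresis, the enzyme quasi-steady-state
## comparison, and posterior correlation structure.

#' Cell-specific reaction rates along a trajectory
#'
#' Applies the rate laws to the simulated concentrations and normalizes by
#' the cell density: `r_j(t) / B(t)` for nitrate reduction, nitrite
#' reduction and aerobic respiration.
#'
#' @param traj a `denit_trajectory`.
#' @param params parameter set; defaults to the trajectory's own.
#' @return data.frame with `time_h`, `r_NO3_per_cell`, `r_NO2_per_cell`,
#'   `r_O2_per_cell` \[mol/(cell s)\].
#' @export
cell_specific_rates <- function(traj, params = traj$params) {
  B <- traj$states[, "B"]
  if (any(B <= 0)) stop("cell density must be positive to normalize rates",
                        call. = FALSE)
  data.frame(time_h = traj$time_h,
             r_NO3_per_cell = traj$derived$r_NO3 / B,
             r_NO2_per_cell = traj$derived$r_NO2 / B,
             r_O2_per_cell = traj$derived$r_O2 / B)
}

#' Predictor-response relation between expression levels and rates
#'
#' Pairs a per-cell predictor series (transcripts, enzymes, or the
#' cell-specific maximum rate) with the corresponding cell-specific
#' substrate turnover rate on the trajectory grid. The traversal order of
#' the pairs is the time order, so the curve traces the induction and
#' decline branches of the relation.
#'
#' @param traj a `denit_trajectory` (enzyme-carrying model for transcript
#'   and enzyme predictors).
#' @param params parameter set; defaults to the trajectory's own.
#' @param predictor `"transcript"`, `"enzyme"` or `"rmax"`.
#' @param reaction `"NAR"` or `"NIR"`.
#' @return object of class `rate_relation`: data.frame with `time_h`,
#'   `predictor`, `response` plus attributes naming the series.
#' @export
rate_relation <- function(traj, params = traj$params,
                          predictor = c("transcript", "enzyme", "rmax"),
                          reaction = c("NAR", "NIR")) {
  predictor <- match.arg(predictor)
  reaction <- match.arg(reaction)
  B <- traj$states[, "B"]
  rates <- cell_specific_rates(traj, params)
  resp <- if (reaction == "NAR") rates$r_NO3_per_cell else rates$r_NO2_per_cell
  pred <- switch(predictor,
    transcript = {
      col <- if (reaction == "NAR") "T_nar_per_cell" else "T_nir_per_cell"
      if (is.null(traj$derived[[col]])) {
        stop("transcript predictor requires an enzyme-carrying model", call. = FALSE)
      }
      traj$derived[[col]]
    },
    enzyme = {
      col <- if (reaction == "NAR") "E_NAR" else "E_NIR"
      if (!col %in% colnames(traj$states)) {
        stop("enzyme predictor requires an enzyme-carrying model", call. = FALSE)
      }
      traj$states[, col] / B
    },
    rmax = {
      col <- if (reaction == "NAR") "rmax_NAR" else "rmax_NIR"
      traj$derived[[col]] / B
    }
  )
  out <- data.frame(time_h = traj$time_h, predictor = pred, response = resp)
  structure(out, class = c("rate_relation", "data.frame"),
            predictor_name = predictor, reaction = reaction)
}

#' Hysteresis index of a predictor-response relation
#'
#' Signed shoelace (polygon) area of the closed path traced by the relation
#' after min-max normalization of both axes, so trajectories of different
#' magnitudes are comparable and the index is invariant under affine
#' rescaling of either axis. A relation that is retraced identically on the
#' way back has zero area; a unit-square counterclockwise loop has area +1.
#'
#' @param series a [rate_relation()] result or any data.frame with columns
#'   `predictor` and `response`.
#' @return dimensionless signed loop area.
#' @export
hysteresis_index <- function(series) {
  x <- series$predictor
  y <- series$response
  stopifnot(length(x) == length(y), length(x) >= 2)
  norm <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) return(rep(0, length(v)))
    (v - r[1]) / (r[2] - r[1])
  }
  x <- norm(x); y <- norm(y)
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  0.5 * sum(x * yn - xn * y)
}

#' Transient vs. quasi-steady-state enzyme comparison
#'
#' Pairs the transient enzyme states with the quasi-steady-state levels
#' computed from the same trajectory ([qss_enzyme_series()]), and reports
#' the maximum QSS/transient ratio during the induction window (times when
#' the QSS level exceeds a small fraction of its maximum). If enzymes
#' equilibrated instantly the pairs would lie on the 1:1 line; a transient
#' pool that lags its quasi-steady state shows up as points below the line
#' on induction and above it on decline (a hysteresis loop).
#'
#' @param traj a `denit_trajectory` from an enzyme-carrying model.
#' @param params parameter set; defaults to the trajectory's own.
#' @param induction_frac fraction of the QSS maximum defining the induction
#'   window.
#' @return list with `series` (per-enzyme data.frame: `time_h`, `transient`,
#'   `qss`), `max_ratio` (named, max QSS/transient during induction) and
#'   `loop_area` (named, hysteresis index of the QSS-transient path).
#' @export
qss_comparison <- function(traj, params = traj$params, induction_frac = 0.05) {
  qss <- qss_enzyme_series(traj, params)
  out <- list(); ratios <- c(); areas <- c()
  for (enz in c("NAR", "NIR")) {
    tr_col <- paste0("E_", enz)
    q <- qss[[paste0("E_", enz, "_qss")]]
    e <- traj$states[, tr_col]
    window <- q > induction_frac * max(q)
    ratios[enz] <- if (any(window)) max(q[window] / pmax(e[window], .Machine$double.xmin))
                   else NA_real_
    areas[enz] <- hysteresis_index(data.frame(predictor = q, response = e))
    out[[enz]] <- data.frame(time_h = traj$time_h, transient = e, qss = q)
  }
  list(series = out, max_ratio = ratios, loop_area = areas)
}

#' Pairwise posterior correlations
#'
#' Pearson correlation matrix across pooled post-warmup draws.
#'
#' @param draws a `posterior_draws` object or chains x draws x parameters
#'   array.
#' @return labeled correlation matrix.
#' @export
posterior_correlations <- function(draws) {
  a <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(length(dim(a)) == 3)
  pooled <- apply(a, 3, as.vector)
  stats::cor(pooled)
}
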