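## Synthetic-experiment generator: produces pseudo-datasets with the same
## structure as the deposited batch experiment (triplicate time series of
## aqueous O2, nitrite, headspace N2, cell density and per-cell narG/nirS
## transcript levels) so the whole calibration pipeline is testable without
## the original data.

#' Observation set
#'
#' Validated container for replicate time-series observations. Values are in
#' the canonical file units (mM for solutes and headspace gases, cells/L,
#' transcripts/cell); `sd` is the replicate standard deviation in Box-Cox
#' transformed space, as consumed by the likelihood.
#'
#' @param data data.frame with columns `variable`, `time_h`, `replicate`,
#'   `value`, `sd`, `unit`.
#' @return object of class `denit_obs`.
#' @export
observation_set <- function(data) {
  req <- c("variable", "time_h", "replicate", "value", "sd", "unit")
  missing <- setdiff(req, names(data))
  if (length(missing)) {
    stop("missing observation columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(data$variable), names(OBS_VARIABLES))
  if (length(bad)) {
    stop("unknown observed variables: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(data$value)) || any(data$value < 0)) {
    stop("observation values must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(data$sd)) || any(data$sd < 0)) {
    stop("observation standard deviations must be finite and non-negative",
         call. = FALSE)
  }
  exp_unit <- OBS_VARIABLES[data$variable]
  if (any(data$unit != exp_unit)) {
    i <- which(data$unit != exp_unit)[1]
    stop(sprintf("unit mismatch for %s: got '%s', canonical unit is '%s'",
                 data$variable[i], data$unit[i], exp_unit[i]), call. = FALSE)
  }
  key <- paste(data$variable, data$time_h, data$replicate)
  if (anyDuplicated(key)) {
    stop("duplicated (variable, time_h, replicate) rows", call. = FALSE)
  }
  n_rep <- stats::aggregate(replicate ~ variable + time_h, data,
                            function(r) length(unique(r)))
  if (any(n_rep$replicate < 2 & data$sd[match(
    paste(n_rep$variable, n_rep$time_h), paste(data$variable, data$time_h))] > 0)) {
    stop("a reported standard deviation requires at least 2 replicates",
         call. = FALSE)
  }
  data <- data[order(data$variable, data$time_h, data$replicate), ]
  rownames(data) <- NULL
  structure(list(data = data), class = "denit_obs")
}

#' @export
print.denit_obs <- function(x, ...) {
  d <- x$data
  cat(sprintf("<denit_obs> %d observations, %d variables, t in [%g, %g] h\n",
              nrow(d), length(unique(d$variable)), min(d$time_h), max(d$time_h)))
  invisible(x)
}

#' Noise configuration of the synthetic experiment
#'
#' Per-variable noise scales in Box-Cox (default: log) space. Transcript
#' noise is multiplicative with a larger scale, reflecting RT-qPCR
#' standard-curve quantification; solute, gas and cell-density measurements
#' are comparatively precise. Transcript values below the detection limit
#' are recorded at the limit.
#'
#' @param scales named per-variable noise scales in transformed space.
#' @param detection_limit_transcripts detection limit \[transcripts/cell\].
#' @param n_replicates replicate count.
#' @return object of class `noise_config`.
#' @export
noise_config <- function(scales = NULL,
                         detection_limit_transcripts = 1e-4,
                         n_replicates = 3) {
  def <- c(O2_aqueous = 0.05, NO2 = 0.05, N2_headspace = 0.05,
           cell_density = 0.05, narG_per_cell = 0.3, nirS_per_cell = 0.3)
  if (!is.null(scales)) {
    stopifnot(all(names(scales) %in% names(def)))
    def[names(scales)] <- scales
  }
  stopifnot_nonneg(scales = def)
  stopifnot(n_replicates >= 2)
  structure(list(scales = def,
                 detection_limit_transcripts = detection_limit_transcripts,
                 n_replicates = n_replicates),
            class = "noise_config")
}

#' Default observation schedule
#'
#' Solutes, gases and cell densities hourly over the run; transcripts at ten
#' unevenly spaced times concentrated around the oxic-anoxic transition,
#' mirroring periodic cell harvests.
#'
#' @param t_end end of the experiment \[hours\].
#' @param transition time of the oxic-anoxic transition \[hours\].
#' @return named list of observation-time vectors per variable.
#' @export
observation_schedule <- function(t_end = 50, transition = 16) {
  hourly <- seq(1, t_end, by = 1)
  transcript_t <- sort(unique(round(c(
    2, 8, transition + c(-2, 0, 2, 4, 7), t_end * c(0.7, 0.85, 1)
  ), 1)))
  list(O2_aqueous = hourly, NO2 = hourly, N2_headspace = hourly,
       cell_density = hourly,
       narG_per_cell = transcript_t, nirS_per_cell = transcript_t)
}

#' Generate a synthetic batch experiment
#'
#' Simulates the chosen model at the true parameters, samples it at the
#' configured observation times and adds independent Student-t (`nu` from
#' the error model, default 10) noise in Box-Cox space per replicate --
#' exactly the noise family the calibration likelihood assumes. Background
#' concentrations are added to oxygen and nitrite before transformation, so
#' generated observations stay positive where the true signal is zero.
#' Per-time replicate standard deviations are computed in transformed space.
#'
#' @param params_true true [parameter_set()].
#' @param setup [reactor_setup()].
#' @param noise [noise_config()].
#' @param model model formulation to simulate.
#' @param schedule observation times per variable
#'   ([observation_schedule()]).
#' @param seed integer seed; fully determines the dataset.
#' @param rtol,atol solver tolerances for the underlying simulation.
#' @return a [observation_set()] object.
#' @export
generate_experiment <- function(params_true, setup = reference_setup(),
                                noise = noise_config(),
                                model = "enzyme",
                                schedule = observation_schedule(),
                                seed = 1, rtol = 1e-10, atol = 1e-12) {
  if (model == "monod") {
    schedule <- schedule[setdiff(names(schedule),
                                 c("narG_per_cell", "nirS_per_cell"))]
  }
  all_t <- sort(unique(c(0, unlist(schedule))))
  traj <- simulate_batch(model, params_true, setup, t_grid = all_t,
                         rtol = rtol, atol = atol)
  err <- params_true$error
  set.seed(seed)
  rows <- list()
  for (v in names(schedule)) {
    m <- .obs_map[[v]]
    sim <- .traj_series(traj, m$col)
    c_true <- stats::approx(traj$time_h, sim, xout = schedule[[v]])$y
    b <- if (!is.na(m$bg)) err[[m$bg]] else 0
    lam <- err$lambda[[v]]
    floor_si <- err$floor[[v]] * m$scale
    mu <- boxcox(pmax(pmax(c_true, 0) + b, floor_si), lam)
    sc <- noise$scales[[v]]
    for (ti in seq_along(mu)) {
      y_rep <- inv_boxcox(mu[ti] + sc * stats::rt(noise$n_replicates, err$nu),
                          lam)
      y_file <- y_rep / m$scale  # SI -> file units
      if (v %in% c("narG_per_cell", "nirS_per_cell")) {
        y_file <- pmax(y_file, noise$detection_limit_transcripts)
      }
      sd_t <- stats::sd(boxcox(y_file * m$scale, lam))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, time_h = schedule[[v]][ti],
        replicate = seq_len(noise$n_replicates),
        value = y_file, sd = sd_t, unit = OBS_VARIABLES[[v]]
      )
    }
  }
  observation_set(do.call(rbind, rows))
}
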