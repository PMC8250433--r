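## Bayesian machinery: Box-Cox transform, composite Student-t likelihood,
## default priors and the free-parameter ledger, a pluggable (gradient-free
## by default) MCMC backend, and rank-normalized split R-hat diagnostics.

#' Box-Cox transform
#'
#' `(y^lambda - 1)/lambda` for `lambda != 0`, `log(y)` at `lambda = 0`;
#' continuous in `lambda`.
#'
#' @param y positive value(s).
#' @param lambda exponent.
#' @return transformed value(s).
#' @export
boxcox <- function(y, lambda) {
  if (any(y < 0)) stop("boxcox requires non-negative arguments", call. = FALSE)
  if (abs(lambda) < 1e-12) {
    if (any(y == 0)) stop("boxcox at lambda = 0 requires strictly positive arguments",
                          call. = FALSE)
    log(y)
  } else {
    (y^lambda - 1) / lambda
  }
}

#' Inverse Box-Cox transform
#'
#' For `lambda > 0` the argument is clamped at the branch point `-1/lambda`,
#' mapping any transformed value below it to zero.
#'
#' @param z transformed value(s).
#' @param lambda exponent.
#' @return value(s) on the original scale.
#' @export
inv_boxcox <- function(z, lambda) {
  if (abs(lambda) < 1e-12) exp(z) else pmax(lambda * z + 1, 0)^(1 / lambda)
}

## Student-t log density with location/scale
t_logdensity <- function(x, mu, sigma, nu) {
  stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma)
}

## map observed variable -> (trajectory column, SI conversion from file
## units, background field)
.obs_map <- list(
  O2_aqueous   = list(col = "C_O2", scale = 1e-3, bg = "b_O2"),
  NO2          = list(col = "C_NO2", scale = 1e-3, bg = "b_NO2"),
  N2_headspace = list(col = "G_N2", scale = 1e-3, bg = NA),
  cell_density = list(col = "B", scale = 1, bg = NA),
  narG_per_cell = list(col = "T_nar_per_cell", scale = 1, bg = NA),
  nirS_per_cell = list(col = "T_nir_per_cell", scale = 1, bg = NA)
)

.traj_series <- function(traj, col) {
  if (col %in% colnames(traj$states)) traj$states[, col] else traj$derived[[col]]
}

#' Log likelihood of an observation set under a simulated trajectory
#'
#' Composite Box-Cox Student-t model: each replicate observation `y_ij` of
#' variable `i` contributes a Student-t log density (degrees of freedom
#' `nu`) of `boxcox(y_ij, lambda_i)` with location `boxcox(c_ij + b_i,
#' lambda_i)` -- the simulated concentration interpolated to the observation
#' time plus a constant background for oxygen and nitrite -- and scale
#' `sigma_ij = sigma_data_ij + sigma_model_i` (arithmetic sum; quadrature if
#' the error model says so). Replicate standard deviations are in
#' transformed space.
#'
#' @param obs a `denit_obs` observation set (see [observation_set()]).
#' @param traj a `denit_trajectory` covering the observation times.
#' @param err an [error_model()].
#' @return total log likelihood (scalar).
#' @export
log_likelihood <- function(obs, traj, err = traj$params$error) {
  df <- obs$data
  total <- 0
  for (v in unique(df$variable)) {
    m <- .obs_map[[v]]
    if (is.null(m)) stop("unknown observed variable: ", v, call. = FALSE)
    sub <- df[df$variable == v, ]
    sim <- .traj_series(traj, m$col)
    if (is.null(sim)) {
      stop(sprintf("trajectory of model '%s' has no simulated counterpart for '%s'",
                   traj$model, v), call. = FALSE)
    }
    rng <- range(sub$time_h)
    if (rng[1] < min(traj$time_h) || rng[2] > max(traj$time_h)) {
      stop("observation times outside the simulated window for ", v, call. = FALSE)
    }
    ## linear dense-output interpolation on the trajectory grid (SI units)
    c_sim <- stats::approx(traj$time_h, sim, xout = sub$time_h)$y
    b <- if (!is.na(m$bg)) err[[m$bg]] else 0
    lam <- err$lambda[[v]]
    ## detection floor: locations and observations below it are censored at
    ## the limit, mirroring how the data are recorded
    floor_si <- err$floor[[v]] * m$scale
    mu <- boxcox(pmax(c_sim + b, floor_si), lam)             # simulated location
    y <- boxcox(pmax(sub$value * m$scale, floor_si), lam)    # observation
    sigma <- if (err$combine == "sum") {
      sub$sd + err$sigma_model[[v]]
    } else {
      sqrt(sub$sd^2 + err$sigma_model[[v]]^2)
    }
    if (any(sigma <= 0)) stop("non-positive observation scale for ", v, call. = FALSE)
    total <- total + sum(t_logdensity(y, mu, sigma, err$nu))
  }
  total
}

## ---- free-parameter ledger and priors ----

#' Default free-parameter ledger
#'
#' The default estimation configuration: a shared block of 11 parameters
#' (per-step rate constant, substrate half-saturation and oxygen inhibition
#' for both reduction steps; respiration/growth `nufix_O2`, `K_O2`, `Y_O2`;
#' backgrounds `b_O2`, `b_NO2`), plus per-variable model-error scales --
#' three for the Monod-type model (14 free parameters in total) and, for the
#' enzyme-based model, the nine regulator kinetic parameters, three
#' operator-binding constants, the two transcript capacities, the enzyme
#' half-life, and six model-error scales (32 in total). Each free parameter
#' carries exactly one prior: log-normal (location at the reference value,
#' one order of magnitude scale) for positive parameters, uniform on
#' \[1, 4\] for Hill coefficients, uniform below the printed detection
#' ceilings for the backgrounds.
#'
#' @param model `"enzyme"` or `"monod"`.
#' @param params reference [parameter_set()] providing prior locations.
#' @return data.frame with columns `name`, `block`, `default`, `dist`,
#'   `arg1`, `arg2` (meanlog/sdlog for `"lognormal"`, bounds for
#'   `"uniform"`).
#' @export
parameter_ledger <- function(model = c("enzyme", "monod"),
                             params = reference_parameters()) {
  model <- match.arg(model)
  kp <- params$kinetics; rp <- params$regulator; ep <- params$expression
  ln <- function(name, block, default, sdlog = 1) {
    data.frame(name = name, block = block, default = default,
               dist = "lognormal", arg1 = log(default), arg2 = sdlog)
  }
  un <- function(name, block, default, a, b) {
    data.frame(name = name, block = block, default = default,
               dist = "uniform", arg1 = a, arg2 = b)
  }
  shared <- rbind(
    if (model == "enzyme") ln("kmax_NAR", "kinetics", kp$kmax_NAR)
    else ln("numax_NAR", "kinetics", kp$numax_NAR),
    if (model == "enzyme") ln("kmax_NIR", "kinetics", kp$kmax_NIR)
    else ln("numax_NIR", "kinetics", kp$numax_NIR),
    ln("K_NO3", "kinetics", kp$K_NO3),
    ln("K_NO2", "kinetics", kp$K_NO2),
    ln("Ireac_NAR", "kinetics", kp$Ireac_NAR),
    ln("Ireac_NIR", "kinetics", kp$Ireac_NIR),
    ln("nufix_O2", "kinetics", kp$nufix_O2),
    ln("K_O2", "kinetics", kp$K_O2),
    ln("Y_O2", "kinetics", kp$Y_O2),
    un("b_O2", "error", params$error$b_O2, 0, 2e-7),
    un("b_NO2", "error", params$error$b_NO2, 0, 1e-7)
  )
  err_vars <- if (model == "monod") {
    c("O2_aqueous", "NO2", "N2_headspace")
  } else {
    names(OBS_VARIABLES)
  }
  err <- do.call(rbind, lapply(err_vars, function(v) {
    ln(paste0("sigma_model_", v), "error", params$error$sigma_model[[v]], 0.5)
  }))
  if (model == "enzyme") {
    reg <- rbind(
      ln("a_NarR_NO3", "regulator", rp$a_NarR_NO3),
      ln("a_NarR_NO2", "regulator", rp$a_NarR_NO2),
      ln("kdec_NarR", "regulator", rp$kdec_NarR),
      ln("I_FnrP", "regulator", rp$I_FnrP),
      un("p", "regulator", rp$p, 1, 4),
      ln("a_NNR", "regulator", rp$a_NNR),
      ln("kdec_NNR", "regulator", rp$kdec_NNR),
      ln("I_NNR", "regulator", rp$I_NNR),
      un("q", "regulator", rp$q, 1, 4),
      ln("K_FnrP", "regulator", rp$K_FnrP),
      ln("K_NarR", "regulator", rp$K_NarR),
      ln("K_NNR", "regulator", rp$K_NNR),
      ln("beta_T_nar", "expression", ep$beta_T_nar),
      ln("beta_T_nir", "expression", ep$beta_T_nir),
      ln("t_half_E_h", "expression", ep$t_half_E_h)
    )
    rbind(shared, reg, err)
  } else {
    rbind(shared, err)
  }
}

#' Apply named parameter values to a parameter set
#'
#' Rebuilds the affected blocks so derived quantities (`kdec_E`,
#' `k_translation`, `numax_O2`, ...) stay consistent with their defining
#' identities.
#'
#' @param params a [parameter_set()].
#' @param values named numeric vector; names follow [parameter_ledger()].
#' @return updated `denit_params`.
#' @export
update_parameters <- function(params, values) {
  stopifnot(!is.null(names(values)), all(nzchar(names(values))))
  rp <- unclass(params$regulator)
  ep <- params$expression
  kp <- unclass(params$kinetics)
  err <- params$error
  ex_args <- list(beta_T_nar = ep$beta_T_nar, beta_T_nir = ep$beta_T_nir,
                  beta_E = ep$beta_E, t_half_E_h = ep$t_half_E_h,
                  t_half_T_min = ep$t_half_T_min)
  for (nm in names(values)) {
    val <- values[[nm]]
    if (nm %in% names(rp)) {
      rp[[nm]] <- val
    } else if (nm %in% names(ex_args)) {
      ex_args[[nm]] <- val
    } else if (nm %in% names(kp)) {
      kp[[nm]] <- val
    } else if (nm %in% c("b_O2", "b_NO2")) {
      err[[nm]] <- val
    } else if (startsWith(nm, "sigma_model_")) {
      v <- sub("^sigma_model_", "", nm)
      if (!v %in% names(err$sigma_model)) stop("unknown variable in ", nm, call. = FALSE)
      err$sigma_model[[v]] <- val
    } else {
      stop("unknown parameter name: ", nm, call. = FALSE)
    }
  }
  parameter_set(
    regulator = do.call(regulator_params, rp[setdiff(names(rp), character(0))][
      c("a_NarR_NO3", "a_NarR_NO2", "kdec_NarR", "I_FnrP", "p", "a_NNR",
        "kdec_NNR", "I_NNR", "q", "K_FnrP", "K_NarR", "K_NNR")]),
    expression = do.call(expression_params, ex_args),
    kinetics = do.call(kinetic_params, kp[
      c("kmax_NAR", "kmax_NIR", "numax_NAR", "numax_NIR", "K_NO3", "K_NO2",
        "Ireac_NAR", "Ireac_NIR", "nufix_O2", "K_O2", "Y_O2", "C_fix")]),
    error = err
  )
}

## transforms between natural and unconstrained sampling space
.to_unconstrained <- function(x, ledger) {
  z <- numeric(nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    z[i] <- if (ledger$dist[i] == "lognormal") log(x[i])
    else stats::qlogis((x[i] - ledger$arg1[i]) / (ledger$arg2[i] - ledger$arg1[i]))
  }
  z
}

.to_natural <- function(z, ledger) {
  x <- numeric(nrow(ledger))
  for (i in seq_len(nrow(ledger))) {
    x[i] <- if (ledger$dist[i] == "lognormal") exp(z[i])
    else ledger$arg1[i] + (ledger$arg2[i] - ledger$arg1[i]) * stats::plogis(z[i])
  }
  stats::setNames(x, ledger$name)
}

.log_prior_unconstrained <- function(z, ledger) {
  lp <- 0
  for (i in seq_len(nrow(ledger))) {
    lp <- lp + if (ledger$dist[i] == "lognormal") {
      stats::dnorm(z[i], ledger$arg1[i], ledger$arg2[i], log = TRUE)
    } else {
      ## uniform on (a, b) mapped through logit: density s(1-s) in z
      stats::plogis(z[i], log.p = TRUE) + stats::plogis(-z[i], log.p = TRUE)
    }
  }
  lp
}

#' Build a log-posterior callable
#'
#' Combines the prior (from the ledger) with [log_likelihood()] evaluated on
#' a fresh simulation for each parameter vector. Parameters are sampled on
#' an unconstrained scale: log for positive (log-normal prior) parameters,
#' logit for bounded (uniform prior) ones.
#'
#' @param model `"enzyme"` or `"monod"`.
#' @param obs observation set.
#' @param params base parameter set; entries not in `free` stay fixed.
#' @param setup reactor setup.
#' @param free character vector of free-parameter names; defaults to the
#'   full ledger of the model.
#' @param ledger prior table from [parameter_ledger()]; rows are subset to
#'   `free`.
#' @param rtol,atol solver tolerances used inside the likelihood; looser
#'   than the display default (the induced log-posterior error is far below
#'   the Monte-Carlo noise) to keep a posterior evaluation cheap.
#' @return list with elements `log_posterior(z)`, `log_prior(z)`, `ledger`,
#'   `to_natural(z)`, `to_unconstrained(x)` and `init` (unconstrained
#'   coordinates of the ledger defaults).
#' @export
build_posterior <- function(model, obs, params, setup = reference_setup(),
                            free = NULL, ledger = parameter_ledger(model, params),
                            rtol = 1e-6, atol = 1e-8) {
  if (!is.null(free)) {
    missing <- setdiff(free, ledger$name)
    if (length(missing)) {
      stop("free parameters not in ledger: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    ledger <- ledger[match(free, ledger$name), ]
  }
  obs_tmax <- max(obs$data$time_h)
  obs_times <- sort(unique(c(0, obs$data$time_h, obs_tmax)))
  log_post <- function(z) {
    lp <- .log_prior_unconstrained(z, ledger)
    if (!is.finite(lp)) return(-Inf)
    x <- .to_natural(z, ledger)
    p <- tryCatch(update_parameters(params, x), error = function(e) NULL)
    if (is.null(p)) return(-Inf)
    traj <- tryCatch(
      simulate_batch(model, p, setup, t_grid = obs_times,
                     rtol = rtol, atol = atol),
      error = function(e) NULL
    )
    if (is.null(traj)) return(-Inf)
    ll <- tryCatch(log_likelihood(obs, traj, p$error), error = function(e) -Inf)
    if (!is.finite(ll)) return(-Inf)
    lp + ll
  }
  list(log_posterior = log_post,
       log_prior = function(z) .log_prior_unconstrained(z, ledger),
       ledger = ledger,
       to_natural = function(z) .to_natural(z, ledger),
       to_unconstrained = function(x) .to_unconstrained(x, ledger),
       init = .to_unconstrained(ledger$default, ledger))
}

#' Sample a posterior with adaptive random-walk Metropolis
#'
#' Gradient-free backend: Gaussian random-walk Metropolis whose proposal
#' covariance and global scale adapt during warmup (empirical covariance of
#' the warmup history, scale tuned toward 30 % acceptance); adaptation is
#' frozen after warmup so the kept draws target the exact posterior. The
#' seed fully determines the output. Chains that never accept are reported
#' in the result, not dropped.
#'
#' @param posterior a [build_posterior()] result, or any list with
#'   `log_posterior` and `init` (and optionally `to_natural`, `ledger`).
#' @param n_chains number of chains (>= 2 for diagnostics).
#' @param n_draws post-warmup draws per chain.
#' @param n_warmup warmup (adaptation) iterations per chain.
#' @param thin keep every `thin`-th post-warmup draw (the chain advances
#'   `n_draws * thin` iterations after warmup).
#' @param seed integer seed.
#' @param init_jitter sd of the Gaussian jitter applied to `init` per chain.
#' @return object of class `posterior_draws`: `draws` array
#'   \[chains, draws, parameters\] on the natural scale, `rhat` per
#'   parameter, `acceptance` per chain, sampler metadata.
#' @export
sample_posterior <- function(posterior, n_chains = 4, n_draws = 1000,
                             n_warmup = 1000, thin = 1, seed = 1,
                             init_jitter = 0.1) {
  stopifnot(n_chains >= 1, n_draws >= 1)
  d <- length(posterior$init)
  to_nat <- posterior$to_natural %||% identity
  par_names <- if (!is.null(posterior$ledger)) posterior$ledger$name
               else paste0("par", seq_len(d))

  draws <- array(NA_real_, dim = c(n_chains, n_draws, d),
                 dimnames = list(NULL, NULL, par_names))
  acceptance <- numeric(n_chains)
  for (ch in seq_len(n_chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    z <- posterior$init + stats::rnorm(d, 0, init_jitter)
    lp <- posterior$log_posterior(z)
    tries <- 0
    while (!is.finite(lp) && tries < 50) {
      z <- posterior$init + stats::rnorm(d, 0, init_jitter)
      lp <- posterior$log_posterior(z)
      tries <- tries + 1
    }
    if (!is.finite(lp)) {
      stop("could not find a finite-posterior starting point for chain ", ch,
           call. = FALSE)
    }
    ## adaptive phase: Robbins-Monro tuning of the global scale toward an
    ## acceptance probability of 0.3, proposal covariance from the full
    ## warmup history; both frozen after warmup
    log_scale <- log(2.38 / sqrt(d)) + log(0.1)
    L <- chol(diag(1, d))
    hist_z <- matrix(NA_real_, n_warmup, d)
    n_acc <- 0; n_tot <- 0
    for (it in seq_len(n_warmup + n_draws * thin)) {
      prop <- z + exp(log_scale) * drop(stats::rnorm(d) %*% L)
      lp_prop <- posterior$log_posterior(prop)
      acc_prob <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
      if (stats::runif(1) < acc_prob) {
        z <- prop; lp <- lp_prop
        if (it > n_warmup) n_acc <- n_acc + 1
      }
      if (it <= n_warmup) {
        hist_z[it, ] <- z
        log_scale <- log_scale + (acc_prob - 0.3) / max(it, 20)^0.6
        if (it >= 200 && it %% 50 == 0) {
          C <- stats::cov(hist_z[seq(max(1, floor(it / 4)), it), , drop = FALSE])
          C <- C + diag(max(diag(C)) * 1e-6 + 1e-12, d)
          Lnew <- tryCatch(chol(C), error = function(e) NULL)
          if (!is.null(Lnew)) {
            if (attr(L, "unit") %||% TRUE) log_scale <- log(2.38 / sqrt(d))
            L <- Lnew
            attr(L, "unit") <- FALSE
          }
        }
      } else {
        n_tot <- n_tot + 1
        if ((it - n_warmup) %% thin == 0) {
          draws[ch, (it - n_warmup) %/% thin, ] <- to_nat(z)
        }
      }
    }
    acceptance[ch] <- n_acc / max(n_tot, 1)
  }
  res <- structure(list(draws = draws, acceptance = acceptance,
                        seed = seed, n_warmup = n_warmup, thin = thin,
                        par_names = par_names),
                   class = "posterior_draws")
  res$rhat <- tryCatch(rhat(res), error = function(e) NULL)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_draws <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("<posterior_draws> %d chains x %d draws x %d parameters\n",
              dm[1], dm[2], dm[3]))
  if (!is.null(x$rhat)) {
    cat("  max split R-hat:", signif(max(x$rhat$rhat, na.rm = TRUE), 4), "\n")
  }
  cat("  acceptance:", paste(signif(x$acceptance, 2), collapse = " "), "\n")
  invisible(x)
}

## classic split R-hat of one parameter given a chains x draws matrix
.split_rhat_basic <- function(m) {
  n <- ncol(m)
  half <- floor(n / 2)
  sub <- rbind(m[, seq_len(half), drop = FALSE],
               m[, (n - half + 1):n, drop = FALSE])
  ch_mean <- rowMeans(sub)
  ch_var <- apply(sub, 1, stats::var)
  W <- mean(ch_var)
  B <- half * stats::var(ch_mean)
  if (W <= 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Rank-normalized split R-hat
#'
#' Convergence diagnostic comparing between-chain to within-chain variance
#' after splitting each chain in half and rank-normalizing the pooled draws;
#' the folded variant (absolute deviations from the median, sensitive to
#' scale differences) is computed as well and the reported value is the
#' maximum of the two. Zero-variance (constant) parameters are flagged as
#' `NA` rather than reported as 1.
#'
#' @param draws a `posterior_draws` object or a chains x draws x parameters
#'   array.
#' @return list with `rhat` (named per-parameter vector) and `max` (headline
#'   value over parameters).
#' @export
rhat <- function(draws) {
  a <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(length(dim(a)) == 3)
  if (dim(a)[1] < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  out <- numeric(dim(a)[3])
  for (j in seq_len(dim(a)[3])) {
    m <- a[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(a)[1])
    if (stats::sd(as.vector(m)) == 0) {
      warning("parameter ", j, " has zero variance across all draws; ",
              "R-hat undefined")
      out[j] <- NA_real_
      next
    }
    zr <- matrix(rank_normalize(as.vector(m)), nrow = nrow(m))
    folded <- abs(m - stats::median(m))
    zf <- matrix(rank_normalize(as.vector(folded)), nrow = nrow(m))
    out[j] <- max(.split_rhat_basic(zr), .split_rhat_basic(zf))
  }
  names(out) <- dimnames(a)[[3]]
  list(rhat = out, max = if (all(is.na(out))) NA_real_ else max(out, na.rm = TRUE))
}
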