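## Stiff integration of the batch-reactor ODE systems. The state is
## integrated as u = ln(x + eps) (configurable), with a variable-order BDF
## solver (deSolve's vode) at tight tolerances; integration restarts at every
## headspace sampling event, which is applied in linear space.

.pack_parms <- function(params, reactor, eps, logspace) {
  rp <- params$regulator; ep <- params$expression; kp <- params$kinetics
  ## layout must match src/denit_rhs.c
  c(rp$a_NarR_NO3, rp$a_NarR_NO2, rp$kdec_NarR, rp$I_FnrP, rp$p,
    rp$a_NNR, rp$kdec_NNR, rp$I_NNR, rp$q, rp$K_FnrP, rp$K_NarR, rp$K_NNR,
    ep$beta_E, ep$kdec_E, kp$kmax_NAR, kp$kmax_NIR, kp$numax_NAR,
    kp$numax_NIR, kp$K_NO3, kp$K_NO2, kp$Ireac_NAR, kp$Ireac_NIR,
    kp$numax_O2, kp$K_O2, kp$Y_O2, reactor$kLa_O2, reactor$kLa_N2,
    reactor$H_O2, reactor$H_N2, reactor$V_liquid / reactor$V_gas,
    eps, as.numeric(logspace),
    1e-4 * rp$K_NarR, 1e-4 * rp$K_NNR)
}

.derivs_name <- function(model) {
  switch(model, enzyme = "derivs_enzyme", monod = "derivs_monod",
         simplified = "derivs_simplified")
}

#' Simulate a batch-reactor experiment
#'
#' Integrates the chosen model formulation over `t_grid`, restarting at each
#' headspace sampling event ([apply_sampling_event()]). By default the state
#' is log-transformed (`u = ln(x + eps)` with floor `eps = 1e-12` in state
#' units, so that states starting at zero are admissible) and solved with a
#' variable-order
#' backward-differentiation formula at absolute and relative tolerance
#' 1e-12.
#'
#' @param model `"enzyme"`, `"monod"` or `"simplified"`.
#' @param params a [parameter_set()] object.
#' @param setup a [reactor_setup()] object.
#' @param t_grid output times \[hours\].
#' @param rtol,atol solver tolerances.
#' @param transform `"log"` (default) or `"linear"` state representation.
#' @param eps log-transform floor in state units.
#' @return object of class `denit_trajectory`: time grid \[hours\], state
#'   matrix in internal SI units, derived series (regulator activities,
#'   promoter activities, per-cell transcripts, reaction rates, capacities),
#'   and the inputs used.
#' @export
simulate_batch <- function(model = c("enzyme", "monod", "simplified"),
                           params, setup = reference_setup(),
                           t_grid = seq(0, 50, by = 0.1),
                           rtol = 1e-12, atol = 1e-12,
                           transform = c("log", "linear"), eps = 1e-12) {
  model <- match.arg(model)
  transform <- match.arg(transform)
  stopifnot(inherits(params, "denit_params"), inherits(setup, "reactor_setup"))
  t_grid <- sort(unique(as.numeric(t_grid)))
  if (t_grid[1] < 0) stop("t_grid must be non-negative", call. = FALSE)

  logspace <- transform == "log"
  snames <- state_names_for(model)
  y0 <- setup$initial_state[snames]
  pv <- .pack_parms(params, setup, eps, logspace)

  t0 <- t_grid[1]
  tmax <- t_grid[length(t_grid)]
  ev <- setup$sampling_times
  ev <- ev[ev > t0 & ev < tmax]
  bounds <- c(t0, ev, tmax)

  encode <- function(x) if (logspace) log(pmax(x, 0) + eps) else x
  decode <- function(u) if (logspace) pmax(exp(u) - eps, 0) else pmax(u, 0)

  out_t <- numeric(0)
  out_y <- NULL
  y <- y0
  for (k in seq_len(length(bounds) - 1L)) {
    a <- bounds[k]; b <- bounds[k + 1L]
    seg_t <- unique(c(a, t_grid[t_grid >= a & t_grid <= b], b))
    sol <- deSolve::ode(
      y = encode(y), times = seg_t * SECONDS_PER_HOUR,
      func = .derivs_name(model), parms = pv,
      dllname = "denitrodyn", initfunc = "denit_initparms",
      method = "vode", rtol = rtol, atol = atol, maxsteps = 50000
    )
    istate <- attr(sol, "istate")[1]
    if (!is.null(istate) && istate < 0) {
      stop(sprintf("ODE solver failed (istate = %d) in segment [%g, %g] h for model '%s'",
                   istate, a, b, model), call. = FALSE)
    }
    if (any(!is.finite(sol[, -1]))) {
      stop("non-finite states produced by the solver; aborting", call. = FALSE)
    }
    dec <- t(apply(sol[, -1, drop = FALSE], 1, decode))
    keep <- seg_t  # vode reports exactly the requested times, in order
    ## report the pre-event state at the segment's right edge; only the
    ## left edge of the following segment sees the event applied
    sel <- keep %in% t_grid
    if (k > 1L) sel[keep == a] <- FALSE
    out_t <- c(out_t, keep[sel])
    out_y <- rbind(out_y, dec[sel, , drop = FALSE])
    y <- stats::setNames(dec[nrow(dec), ], snames)
    if (b %in% setup$sampling_times) y <- apply_sampling_event(y, setup)
  }
  colnames(out_y) <- snames
  traj <- structure(list(model = model, time_h = out_t, states = out_y,
                         params = params, setup = setup,
                         transform = transform, eps = eps,
                         rtol = rtol, atol = atol),
                    class = "denit_trajectory")
  traj$derived <- trajectory_derived(traj)
  traj
}

#' Derived series of a trajectory
#'
#' Recomputes, purely from the stored states and parameters, the regulator
#' activities, promoter activities, per-cell and per-liter quasi-steady-state
#' transcript levels, reaction rates and maximum capacities along the grid.
#' Being a pure function of (states, parameters), repeated evaluation is
#' bit-identical.
#'
#' @param traj a `denit_trajectory`.
#' @return data.frame aligned with the trajectory grid.
#' @export
trajectory_derived <- function(traj) {
  s <- traj$states
  params <- traj$params
  kp <- params$kinetics; rp <- params$regulator; ep <- params$expression
  B <- s[, "B"]
  r_O2 <- respiration_rate(B, s[, "C_O2"], kp)
  d <- data.frame(time_h = traj$time_h, r_O2 = r_O2)

  if (traj$model == "monod") {
    d$rmax_NAR <- kp$numax_NAR * B
    d$rmax_NIR <- kp$numax_NIR * B
  } else {
    d$rmax_NAR <- rmax_enzyme(kp$kmax_NAR, s[, "E_NAR"])
    d$rmax_NIR <- rmax_enzyme(kp$kmax_NIR, s[, "E_NIR"])
  }
  d$r_NO3 <- reduction_rate(s[, "C_NO3"], s[, "C_O2"], d$rmax_NAR,
                            kp$K_NO3, kp$Ireac_NAR)
  d$r_NO2 <- reduction_rate(s[, "C_NO2"], s[, "C_O2"], d$rmax_NIR,
                            kp$K_NO2, kp$Ireac_NIR)

  if (traj$model == "enzyme") {
    d$X_FnrP <- fnrp_active(s[, "C_O2"], rp)
    d$X_NNR <- nnr_active(s[, "Xhat_NNR"], s[, "C_O2"], rp)
    d$f_act_nar <- promoter_activity_nar(d$X_FnrP, s[, "X_NarR"], rp)
    d$f_act_nir <- promoter_activity_nir(d$X_NNR, rp)
  } else if (traj$model == "simplified") {
    act <- activities_simplified(s[, "C_O2"], s[, "C_NO3"], s[, "C_NO2"], rp)
    d$f_act_nar <- act$f_act_nar
    d$f_act_nir <- act$f_act_nir
  }
  if (traj$model != "monod") {
    d$T_nar_per_L <- transcript_qss(d$f_act_nar, B, ep$beta_T_nar)
    d$T_nir_per_L <- transcript_qss(d$f_act_nir, B, ep$beta_T_nir)
    d$T_nar_per_cell <- ifelse(B > 0, d$T_nar_per_L / B, 0)
    d$T_nir_per_cell <- ifelse(B > 0, d$T_nir_per_L / B, 0)
  }
  d
}

#' @export
print.denit_trajectory <- function(x, ...) {
  cat(sprintf("<denit_trajectory> model=%s, %d time points over [%g, %g] h\n",
              x$model, length(x$time_h), min(x$time_h), max(x$time_h)))
  invisible(x)
}

#' @export
as.data.frame.denit_trajectory <- function(x, ...) {
  cbind(data.frame(time_h = x$time_h), as.data.frame(x$states),
        x$derived[, setdiff(names(x$derived), "time_h"), drop = FALSE])
}

#' Quasi-steady-state enzyme series along a trajectory
#'
#' The enzyme level each pool would hold if it equilibrated instantly to the
#' current promoter activity and cell density: `E_qss = beta_E * f_act * B`.
#' Comparing this with the transient enzyme states tests the enzyme
#' quasi-steady-state assumption.
#'
#' @param traj a `denit_trajectory` from the enzyme-based or simplified model.
#' @param params parameter set; defaults to the trajectory's own.
#' @return data.frame with `time_h`, `E_NAR_qss`, `E_NIR_qss` \[enzymes/L\].
#' @export
qss_enzyme_series <- function(traj, params = traj$params) {
  if (traj$model == "monod") {
    stop("QSS enzyme series is defined for enzyme-carrying models only",
         call. = FALSE)
  }
  ep <- params$expression
  B <- traj$states[, "B"]
  data.frame(time_h = traj$time_h,
             E_NAR_qss = ep$beta_E * traj$derived$f_act_nar * B,
             E_NIR_qss = ep$beta_E * traj$derived$f_act_nir * B)
}

#' Explicitly integrated transcript series (quasi-steady-state oracle)
#'
#' Integrates the full transcript balance `dT/dt = alpha * f_act * B -
#' kdec_T * T` with a finite transcript decay rate along a stored
#' trajectory, interpolating `f_act * B` linearly between grid points. As
#' `kdec_T` grows (transcript half-life shrinks), this converges to the
#' quasi-steady-state series `beta_T * f_act * B` used by the production
#' model.
#'
#' @param traj a `denit_trajectory` (enzyme or simplified model).
#' @param gene `"nar"` or `"nir"`.
#' @param kdec_T transcript decay rate \[1/s\]; defaults to the parameter
#'   set's value (3 min half-life).
#' @return data.frame with `time_h`, `T_per_L`, `T_qss_per_L`.
#' @export
transcript_transient_series <- function(traj, gene = c("nar", "nir"),
                                        kdec_T = traj$params$expression$kdec_T) {
  gene <- match.arg(gene)
  ep <- traj$params$expression
  beta_T <- if (gene == "nar") ep$beta_T_nar else ep$beta_T_nir
  f_col <- paste0("f_act_", gene)
  drive <- traj$derived[[f_col]] * traj$states[, "B"]
  t_s <- traj$time_h * SECONDS_PER_HOUR
  drive_fun <- stats::approxfun(t_s, drive, rule = 2)
  alpha <- beta_T * kdec_T
  rhs <- function(t, y, p) list(alpha * drive_fun(t) - kdec_T * y)
  sol <- deSolve::ode(y = c(T = drive[1] * beta_T), times = t_s, func = rhs,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-6)
  data.frame(time_h = traj$time_h, T_per_L = sol[, 2],
             T_qss_per_L = beta_T * drive)
}
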