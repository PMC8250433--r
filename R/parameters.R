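## Parameter containers. Internally everything is SI: mol/L, seconds,
## per-liter counts. User-facing constructors accept the experiment-scale
## units that appear in data files (hours for half-lives) and convert here.

#' Transcription-factor (regulator) parameters
#'
#' Kinetic and equilibrium constants of the three regulators gating
#' denitrification gene expression in *P. denitrificans*: FnrP (oxygen
#' sensing, equilibrium Hill inactivation), NarR (activated by nitrate and
#' nitrite) and NNR (activated by nitrite, inactivated by oxygen at
#' equilibrium).
#'
#' @param a_NarR_NO3,a_NarR_NO2 NarR activation rate constants by nitrate and
#'   nitrite \[1/(M s)\].
#' @param kdec_NarR NarR deactivation (dissociation) rate \[1/s\].
#' @param I_FnrP FnrP oxygen inhibition constant \[M\].
#' @param p FnrP Hill coefficient (>= 1, dimensionless).
#' @param a_NNR NNR activation rate constant by nitrite \[1/(M s)\].
#' @param kdec_NNR NNR deactivation rate \[1/s\].
#' @param I_NNR NNR oxygen inhibition constant \[M\].
#' @param q NNR Hill coefficient (>= 1).
#' @param K_FnrP,K_NarR,K_NNR operator-binding half-saturation constants
#'   relative to total regulator concentration (dimensionless).
#' @return object of class `regulator_params`.
#' @export
regulator_params <- function(a_NarR_NO3, a_NarR_NO2, kdec_NarR,
                             I_FnrP, p, a_NNR, kdec_NNR, I_NNR, q,
                             K_FnrP, K_NarR, K_NNR) {
  stopifnot_positive(a_NarR_NO3 = a_NarR_NO3, a_NarR_NO2 = a_NarR_NO2,
                     kdec_NarR = kdec_NarR, I_FnrP = I_FnrP, p = p,
                     a_NNR = a_NNR, kdec_NNR = kdec_NNR, I_NNR = I_NNR,
                     q = q, K_FnrP = K_FnrP, K_NarR = K_NarR, K_NNR = K_NNR)
  if (p < 1 || q < 1) stop("Hill coefficients p and q must be >= 1", call. = FALSE)
  structure(list(a_NarR_NO3 = a_NarR_NO3, a_NarR_NO2 = a_NarR_NO2,
                 kdec_NarR = kdec_NarR, I_FnrP = I_FnrP, p = p,
                 a_NNR = a_NNR, kdec_NNR = kdec_NNR, I_NNR = I_NNR, q = q,
                 K_FnrP = K_FnrP, K_NarR = K_NarR, K_NNR = K_NNR),
            class = "regulator_params")
}

#' Gene-expression parameters
#'
#' Transcript capacities and enzyme turnover of the expression cascade. The
#' translation rate constant is not a free parameter: it is tied to the
#' maximum quasi-steady-state per-cell enzyme level `beta_E` through
#' `k_translation_i = kdec_E * beta_E / beta_T_i`, so that at full promoter
#' activation the enzyme quasi-steady state equals `beta_E` enzymes per cell.
#' The transcript decay rate `kdec_T` does not enter the production model
#' (transcripts are at quasi-steady state, where it cancels); it is carried
#' for the explicitly integrated transcript oracle.
#'
#' @param beta_T_nar,beta_T_nir maximum per-cell transcript levels
#'   \[transcripts/cell\].
#' @param beta_E maximum quasi-steady-state per-cell enzyme level
#'   \[enzymes/cell\]; fixed at 1125 by default because enzyme levels are
#'   unidentifiable jointly with kmax.
#' @param t_half_E_h enzyme half-life \[hours\] (user-facing; converted to
#'   the decay rate `kdec_E = ln 2 / t_half`).
#' @param t_half_T_min transcript half-life \[minutes\], oracle only.
#' @return object of class `expression_params` with derived fields
#'   `kdec_E`, `kdec_T`, `alpha_nar`, `alpha_nir`, `k_translation_nar`,
#'   `k_translation_nir`.
#' @export
expression_params <- function(beta_T_nar, beta_T_nir, beta_E = 1125,
                              t_half_E_h = 3, t_half_T_min = 3) {
  stopifnot_positive(beta_T_nar = beta_T_nar, beta_T_nir = beta_T_nir,
                     beta_E = beta_E, t_half_E_h = t_half_E_h,
                     t_half_T_min = t_half_T_min)
  kdec_E <- log(2) / (t_half_E_h * SECONDS_PER_HOUR)
  kdec_T <- log(2) / (t_half_T_min * 60)
  structure(list(
    beta_T_nar = beta_T_nar, beta_T_nir = beta_T_nir, beta_E = beta_E,
    t_half_E_h = t_half_E_h, kdec_E = kdec_E,
    t_half_T_min = t_half_T_min, kdec_T = kdec_T,
    alpha_nar = beta_T_nar * kdec_T,
    alpha_nir = beta_T_nir * kdec_T,
    k_translation_nar = kdec_E * beta_E / beta_T_nar,
    k_translation_nir = kdec_E * beta_E / beta_T_nir
  ), class = "expression_params")
}

#' Reaction-kinetic parameters
#'
#' Michaelis-Menten constants of the two reduction steps, aerobic respiration
#' and growth. The respiration capacity is parameterized by the cell-specific
#' rate `nufix_O2` at a fixed reference oxygen concentration `C_fix` rather
#' than by the saturation rate `numax_O2`; the latter is derived as
#' `numax_O2 = nufix_O2 * (C_fix + K_O2) / C_fix`. This reparameterization
#' decorrelates the rate capacity from `K_O2` during calibration. `C_fix`
#' defaults to the air-saturated initial oxygen level, the only distinguished
#' oxygen concentration of the experiment.
#'
#' @param kmax_NAR,kmax_NIR enzyme turnover numbers \[substrate molecules per
#'   enzyme per second\]; enzyme-based model only.
#' @param numax_NAR,numax_NIR cell-specific maximum rates \[mol/(cell s)\];
#'   Monod-type model only.
#' @param K_NO3,K_NO2 substrate half-saturation constants \[M\].
#' @param Ireac_NAR,Ireac_NIR kinetic oxygen inhibition constants \[M\].
#' @param nufix_O2 cell-specific respiration rate at `C_fix` \[mol/(cell s)\].
#' @param K_O2 oxygen half-saturation constant \[M\].
#' @param Y_O2 growth yield \[cells per mol succinate\].
#' @param C_fix reference oxygen concentration \[M\].
#' @return object of class `kinetic_params`, including derived `numax_O2`
#'   and the immutable stoichiometric coefficients `n_succ = 2`, `n_O2 = 7`.
#' @export
kinetic_params <- function(kmax_NAR, kmax_NIR, numax_NAR, numax_NIR,
                           K_NO3, K_NO2, Ireac_NAR, Ireac_NIR,
                           nufix_O2, K_O2, Y_O2, C_fix = 2.5e-4) {
  stopifnot_positive(kmax_NAR = kmax_NAR, kmax_NIR = kmax_NIR,
                     numax_NAR = numax_NAR, numax_NIR = numax_NIR,
                     K_NO3 = K_NO3, K_NO2 = K_NO2,
                     Ireac_NAR = Ireac_NAR, Ireac_NIR = Ireac_NIR,
                     nufix_O2 = nufix_O2, K_O2 = K_O2, Y_O2 = Y_O2,
                     C_fix = C_fix)
  structure(list(kmax_NAR = kmax_NAR, kmax_NIR = kmax_NIR,
                 numax_NAR = numax_NAR, numax_NIR = numax_NIR,
                 K_NO3 = K_NO3, K_NO2 = K_NO2,
                 Ireac_NAR = Ireac_NAR, Ireac_NIR = Ireac_NIR,
                 nufix_O2 = nufix_O2, K_O2 = K_O2, Y_O2 = Y_O2,
                 C_fix = C_fix,
                 numax_O2 = nufix_O2 * (C_fix + K_O2) / C_fix,
                 n_succ = N_SUCC, n_O2 = N_O2),
            class = "kinetic_params")
}

#' Observation error model
#'
#' Composite Student-t error model in Box-Cox space. Residuals are formed
#' between Box-Cox-transformed observations and the transformed simulated
#' concentration plus a small constant background (`b_O2`, `b_NO2`) that
#' represents the detection floor of oxygen and nitrite measurements. The
#' scale of each observation is the arithmetic sum of its replicate data
#' error and a per-variable model-structural error (a quadrature combination
#' is available via `combine = "quadrature"`).
#'
#' @param nu Student-t degrees of freedom (default 10).
#' @param lambda named Box-Cox exponent per observed variable. Default 0
#'   (log transform) everywhere except headspace N2, which uses 0.25 so
#'   that the exact zeros before denitrification starts remain admissible.
#' @param b_O2,b_NO2 background concentrations \[M\] added to simulated O2
#'   and nitrite; priors bound them below 2e-7 and 1e-7 M respectively.
#' @param sigma_model named per-variable model-structural error scales (in
#'   transformed space).
#' @param floor named per-variable detection floor (canonical file units);
#'   simulated locations and observations below it are censored at the
#'   limit. Default: 1e-4 transcripts/cell for the transcript variables.
#' @param combine how data and model errors combine: `"sum"` (default) or
#'   `"quadrature"`.
#' @return object of class `error_model`.
#' @export
error_model <- function(nu = 10,
                        lambda = NULL,
                        b_O2 = 5e-8, b_NO2 = 2e-8,
                        sigma_model = NULL,
                        floor = NULL,
                        combine = c("sum", "quadrature")) {
  combine <- match.arg(combine)
  vars <- names(OBS_VARIABLES)
  lam <- stats::setNames(rep(0, length(vars)), vars)
  lam["N2_headspace"] <- 0.25
  if (!is.null(lambda)) {
    stopifnot(all(names(lambda) %in% vars))
    lam[names(lambda)] <- lambda
  }
  sm <- stats::setNames(rep(0.1, length(vars)), vars)
  if (!is.null(sigma_model)) {
    stopifnot(all(names(sigma_model) %in% vars))
    sm[names(sigma_model)] <- sigma_model
  }
  fl <- stats::setNames(rep(0, length(vars)), vars)
  fl[c("narG_per_cell", "nirS_per_cell")] <- 1e-4
  if (!is.null(floor)) {
    stopifnot(all(names(floor) %in% vars))
    fl[names(floor)] <- floor
  }
  stopifnot_nonneg(b_O2 = b_O2, b_NO2 = b_NO2, sigma_model = sm, floor = fl)
  stopifnot_positive(nu = nu)
  structure(list(nu = nu, lambda = lam, b_O2 = b_O2, b_NO2 = b_NO2,
                 sigma_model = sm, floor = fl, combine = combine),
            class = "error_model")
}

#' Assemble a full parameter set
#'
#' @param regulator a [regulator_params()] object.
#' @param expression an [expression_params()] object.
#' @param kinetics a [kinetic_params()] object.
#' @param error an [error_model()] object.
#' @return object of class `denit_params`.
#' @export
parameter_set <- function(regulator, expression, kinetics, error = error_model()) {
  stopifnot(inherits(regulator, "regulator_params"),
            inherits(expression, "expression_params"),
            inherits(kinetics, "kinetic_params"),
            inherits(error, "error_model"))
  structure(list(regulator = regulator, expression = expression,
                 kinetics = kinetics, error = error),
            class = "denit_params")
}

#' @export
print.denit_params <- function(x, ...) {
  cat("<denit_params>\n")
  for (block in c("regulator", "expression", "kinetics")) {
    v <- unlist(x[[block]])
    cat(" ", block, ": ", paste0(names(v), "=", signif(v, 4), collapse = ", "),
        "\n", sep = "")
  }
  cat("  error: nu=", x$error$nu, ", combine=", x$error$combine, "\n", sep = "")
  invisible(x)
}

#' Reference parameter set
#'
#' A documented default parameterization whose enzyme-based simulation
#' reproduces the canonical dynamics of the succinate batch experiment:
#' an oxic phase of roughly half a day during which narG transcripts sit at
#' a baseline near 1e-2 per cell, complete nitrate-to-nitrite conversion
#' before nitrite reduction sets in, a nitrite peak at the initial nitrate
#' level (2 mM, around 25 h) and complete denitrification within 50 h.
#' Magnitudes are anchored to literature scales: transcript half-life of
#' minutes, enzyme half-life of hours, turnover numbers of order 100/s,
#' per-cell respiration of order 1e-19 mol/(cell s).
#'
#' @return a [parameter_set()] object.
#' @export
reference_parameters <- function() {
  parameter_set(
    regulator = regulator_params(
      a_NarR_NO3 = 1.0, a_NarR_NO2 = 1.0, kdec_NarR = 2e-4,
      I_FnrP = 2.5e-6, p = 2,
      a_NNR = 0.2, kdec_NNR = 2e-4, I_NNR = 2.5e-7, q = 2,
      K_FnrP = 0.05, K_NarR = 0.1, K_NNR = 1
    ),
    expression = expression_params(
      beta_T_nar = 3, beta_T_nir = 3, beta_E = 1125,
      t_half_E_h = 3, t_half_T_min = 3
    ),
    kinetics = kinetic_params(
      kmax_NAR = 800, kmax_NIR = 350,
      numax_NAR = 6e-19, numax_NIR = 1.2e-19,
      K_NO3 = 5e-5, K_NO2 = 5e-5,
      Ireac_NAR = 2e-6, Ireac_NIR = 2e-7,
      nufix_O2 = 6e-19, K_O2 = 1e-5, Y_O2 = 1e14,
      C_fix = 2.5e-4
    ),
    error = error_model()
  )
}
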