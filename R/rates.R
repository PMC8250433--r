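## Rate laws and right-hand-side terms. These R functions are the reference
## definitions of every process; the compiled solver core (src/denit_rhs.c)
## mirrors them and is cross-checked against them in the tests.

#' Time derivative of the active NarR fraction
#'
#' `dX/dt = (a_NO3*C_NO3 + a_NO2*C_NO2)*(1 - X) - kdec*X`: activation of the
#' inactive pool by nitrate and nitrite, first-order deactivation.
#'
#' @param X_NarR active fraction in \[0, 1\].
#' @param C_NO3,C_NO2 nitrate and nitrite concentrations \[M\].
#' @param params a [regulator_params()] object.
#' @return rate \[1/s\].
#' @export
narr_derivative <- function(X_NarR, C_NO3, C_NO2, params) {
  stopifnot_nonneg(C_NO3 = C_NO3, C_NO2 = C_NO2)
  if (any(X_NarR < 0 | X_NarR > 1)) stop("X_NarR must lie in [0, 1]", call. = FALSE)
  (params$a_NarR_NO3 * C_NO3 + params$a_NarR_NO2 * C_NO2) * (1 - X_NarR) -
    params$kdec_NarR * X_NarR
}

#' Active FnrP fraction (equilibrium oxygen inactivation)
#'
#' Hill function `I^p / (I^p + C_O2^p)`: fully active when anoxic, half
#' active at `C_O2 = I_FnrP`.
#'
#' @param C_O2 oxygen concentration \[M\].
#' @inheritParams narr_derivative
#' @return fraction in \[0, 1\].
#' @export
fnrp_active <- function(C_O2, params) {
  stopifnot_nonneg(C_O2 = C_O2)
  hill_inhibition(C_O2, params$I_FnrP, params$p)
}

hill_inhibition <- function(C, I, n) {
  ## written with the ratio to stay finite for extreme C/I
  1 / (1 + (C / I)^n)
}

#' Time derivative of the nitrite-activated NNR fraction
#'
#' Same structure as [narr_derivative()] with activation by nitrite only;
#' oxygen inactivation is applied at equilibrium in [nnr_active()].
#'
#' @param Xhat nitrite-activated fraction (before oxygen inactivation).
#' @inheritParams narr_derivative
#' @return rate \[1/s\].
#' @export
nnr_derivative <- function(Xhat, C_NO2, params) {
  stopifnot_nonneg(C_NO2 = C_NO2)
  if (any(Xhat < 0 | Xhat > 1)) stop("Xhat must lie in [0, 1]", call. = FALSE)
  params$a_NNR * C_NO2 * (1 - Xhat) - params$kdec_NNR * Xhat
}

#' Active NNR fraction after equilibrium oxygen inactivation
#'
#' @inheritParams nnr_derivative
#' @inheritParams fnrp_active
#' @return fraction in \[0, 1\].
#' @export
nnr_active <- function(Xhat, C_O2, params) {
  stopifnot_nonneg(C_O2 = C_O2)
  hill_inhibition(C_O2, params$I_NNR, params$q) * Xhat
}

#' narG promoter activity
#'
#' Fraction of nar operator sites with both FnrP and NarR bound, from the
#' two-activator equilibrium binding polynomial with relative half-saturation
#' constants `K_FnrP` and `K_NarR`.
#'
#' @param X_FnrP,X_NarR active regulator fractions.
#' @inheritParams narr_derivative
#' @return activity in \[0, 1).
#' @export
promoter_activity_nar <- function(X_FnrP, X_NarR, params) {
  u <- X_FnrP / params$K_FnrP
  v <- X_NarR / params$K_NarR
  (u * v) / (1 + u + v + u * v)
}

#' nirS promoter activity
#'
#' Single-activator saturation `X_NNR / (X_NNR + K_NNR)`.
#'
#' @param X_NNR active NNR fraction.
#' @inheritParams narr_derivative
#' @return activity in \[0, 1).
#' @export
promoter_activity_nir <- function(X_NNR, params) {
  X_NNR / (X_NNR + params$K_NNR)
}

#' Quasi-steady-state transcript concentration
#'
#' Transcripts equilibrate within minutes, much faster than enzymes or
#' substrates, so their balance of transcription (`alpha * f_act * B`) and
#' first-order decay gives `T_qss = beta_T * f_act * B` with
#' `beta_T = alpha / kdec_T`. The decay rate cancels.
#'
#' @param f_act promoter activity in \[0, 1\].
#' @param B cell density \[cells/L\].
#' @param beta_T maximum per-cell transcript level \[transcripts/cell\].
#' @return transcript concentration \[transcripts/L\].
#' @export
transcript_qss <- function(f_act, B, beta_T) {
  stopifnot_nonneg(f_act = f_act, B = B, beta_T = beta_T)
  beta_T * f_act * B
}

#' Time derivative of an enzyme pool
#'
#' Translation at the quasi-steady-state transcript level minus first-order
#' decay. Substituting the transcript quasi-steady state and the tied
#' translation constant `k_translation = kdec_E * beta_E / beta_T` collapses
#' the balance to `dE/dt = kdec_E * (beta_E * f_act * B - E)`: relaxation
#' toward the enzyme quasi-steady state with rate `kdec_E`.
#'
#' @param E enzyme concentration \[enzymes/L\].
#' @param f_act promoter activity.
#' @param B cell density \[cells/L\].
#' @param params an [expression_params()] object.
#' @return rate \[enzymes/(L s)\].
#' @export
enzyme_derivative <- function(E, f_act, B, params) {
  stopifnot_nonneg(E = E, f_act = f_act, B = B)
  params$kdec_E * (params$beta_E * f_act * B - E)
}

#' Substrate reduction rate (Michaelis-Menten with oxygen inhibition)
#'
#' `rate = r_max * C/(C + K) * I/(I + C_O2)`. The capacity `r_max` \[mol/(L s)\]
#' is `numax * B` in the Monod-type model or `kmax * E / N_A` in the
#' enzyme-based model (the Avogadro factor converts the per-liter enzyme
#' count to moles; see [rmax_enzyme()]).
#'
#' @param C_sub substrate concentration \[M\].
#' @param C_O2 oxygen concentration \[M\].
#' @param r_max maximum rate \[mol/(L s)\].
#' @param K_sub substrate half-saturation \[M\].
#' @param I_reac oxygen inhibition constant \[M\].
#' @return rate \[mol/(L s)\].
#' @export
reduction_rate <- function(C_sub, C_O2, r_max, K_sub, I_reac) {
  stopifnot_nonneg(C_sub = C_sub, C_O2 = C_O2)
  r_max * C_sub / (C_sub + K_sub) * I_reac / (I_reac + C_O2)
}

#' Maximum rate of an enzyme pool
#'
#' `r_max = kmax * E / N_A`: turnover number \[molecules/(enzyme s)\] times
#' enzyme count \[enzymes/L\], converted to \[mol/(L s)\].
#'
#' @param kmax turnover number \[1/s\].
#' @param E enzyme concentration \[enzymes/L\].
#' @return maximum rate \[mol/(L s)\].
#' @export
rmax_enzyme <- function(kmax, E) {
  kmax * E / N_AVOGADRO
}

#' Aerobic respiration rate
#'
#' Monod rate law `numax_O2 * B * C_O2 / (C_O2 + K_O2)`, where `numax_O2` is
#' derived from the reparameterized capacity `nufix_O2` at the reference
#' concentration `C_fix` (see [kinetic_params()]).
#'
#' @param B cell density \[cells/L\].
#' @param C_O2 oxygen concentration \[M\].
#' @param params a [kinetic_params()] object.
#' @return rate \[mol O2/(L s)\].
#' @export
respiration_rate <- function(B, C_O2, params) {
  stopifnot_nonneg(B = B, C_O2 = C_O2)
  params$numax_O2 * B * C_O2 / (C_O2 + params$K_O2)
}

#' Growth rate coupled to aerobic respiration
#'
#' Growth occurs on aerobic respiration only:
#' `dB/dt = Y_O2 * (n_succ/n_O2) * r_O2 = Y_O2 * (2/7) * r_O2`, with the
#' stoichiometric ratio fixed by the balanced energy reaction
#' (see [respiration_stoichiometry()]).
#'
#' @param r_O2 respiration rate \[mol O2/(L s)\].
#' @inheritParams respiration_rate
#' @return rate \[cells/(L s)\].
#' @export
growth_rate <- function(r_O2, params) {
  stopifnot_nonneg(r_O2 = r_O2)
  params$Y_O2 * (params$n_succ / params$n_O2) * r_O2
}

## ---- promoter activities from a full state ----

activities_enzyme <- function(state, params) {
  rp <- params$regulator
  X_FnrP <- fnrp_active(state[["C_O2"]], rp)
  X_NNR <- nnr_active(state[["Xhat_NNR"]], state[["C_O2"]], rp)
  list(X_FnrP = X_FnrP, X_NNR = X_NNR,
       f_act_nar = promoter_activity_nar(X_FnrP, state[["X_NarR"]], rp),
       f_act_nir = promoter_activity_nir(X_NNR, rp))
}

#' Promoter activities of the simplified (regulator-free) model
#'
#' A reduced transcription description in which promoter activities depend
#' directly on the signaling concentrations, with no regulator state and
#' hence no activation lag:
#' `f_act_nar = HillO2(I_FnrP, p) * (C_NO3 + C_NO2)/(C_NO3 + C_NO2 + K_N)`
#' and `f_act_nir = HillO2(I_NNR, q) * C_NO2/(C_NO2 + K_N2)`.
#' This functional form is this package's reconstruction of a regulator-free
#' transcription variant; it shares the oxygen Hill factors with the full
#' model, and `K_N`, `K_N2` default to the operator constants `K_NarR`,
#' `K_NNR` mapped onto a 1e-4 M concentration scale.
#'
#' @param C_O2,C_NO3,C_NO2 concentrations \[M\].
#' @param params a [regulator_params()] object.
#' @param K_N,K_N2 half-saturation concentrations \[M\] of the direct
#'   substrate dependence.
#' @return list with `f_act_nar`, `f_act_nir`.
#' @export
activities_simplified <- function(C_O2, C_NO3, C_NO2, params,
                                  K_N = 1e-4 * params$K_NarR,
                                  K_N2 = 1e-4 * params$K_NNR) {
  N_ox <- C_NO3 + C_NO2
  list(
    f_act_nar = hill_inhibition(C_O2, params$I_FnrP, params$p) *
      N_ox / (N_ox + K_N),
    f_act_nir = hill_inhibition(C_O2, params$I_NNR, params$q) *
      C_NO2 / (C_NO2 + K_N2)
  )
}

## ---- assembled right-hand sides (reference R implementation) ----

core_solute_derivs <- function(state, r_O2, r_NO3, r_NO2, params, reactor) {
  tr_O2 <- gas_transfer_rate(state[["C_O2"]], state[["G_O2"]],
                             reactor$kLa_O2, reactor$H_O2)
  tr_N2 <- gas_transfer_rate(state[["C_N2"]], state[["G_N2"]],
                             reactor$kLa_N2, reactor$H_N2)
  ratio <- reactor$V_liquid / reactor$V_gas
  c(C_O2 = -r_O2 + tr_O2,
    C_NO3 = -r_NO3,
    C_NO2 = r_NO3 - r_NO2,
    C_N2 = 0.5 * r_NO2 + tr_N2,
    G_O2 = -ratio * tr_O2,
    G_N2 = -ratio * tr_N2,
    B = growth_rate(r_O2, params$kinetics))
}

check_finite_derivs <- function(d) {
  if (any(!is.finite(d))) {
    stop("non-finite derivative components: ",
         paste(names(d)[!is.finite(d)], collapse = ", "), call. = FALSE)
  }
  d
}

#' Right-hand side of the enzyme-based model
#'
#' Assembles all state derivatives: regulator activation, enzyme
#' production/decay at quasi-steady-state transcript levels, the two
#' reduction steps with enzyme-proportional capacities, aerobic respiration,
#' growth, and gas exchange. In a closed liquid-only system the assembled
#' derivatives conserve nitrogen: `d/dt (C_NO3 + C_NO2 + 2 C_N2) = 0`.
#'
#' @param state named numeric state vector (see `reference_setup()` for the
#'   layout).
#' @param params a [parameter_set()] object.
#' @param reactor a [reactor_setup()] object.
#' @return named numeric vector of derivatives, same layout as `state`.
#' @export
rhs_enzyme_model <- function(state, params, reactor) {
  kp <- params$kinetics
  act <- activities_enzyme(state, params)
  r_O2 <- respiration_rate(state[["B"]], state[["C_O2"]], kp)
  r_NO3 <- reduction_rate(state[["C_NO3"]], state[["C_O2"]],
                          rmax_enzyme(kp$kmax_NAR, state[["E_NAR"]]),
                          kp$K_NO3, kp$Ireac_NAR)
  r_NO2 <- reduction_rate(state[["C_NO2"]], state[["C_O2"]],
                          rmax_enzyme(kp$kmax_NIR, state[["E_NIR"]]),
                          kp$K_NO2, kp$Ireac_NIR)
  d <- c(core_solute_derivs(state, r_O2, r_NO3, r_NO2, params, reactor),
         X_NarR = narr_derivative(state[["X_NarR"]], state[["C_NO3"]],
                                  state[["C_NO2"]], params$regulator),
         Xhat_NNR = nnr_derivative(state[["Xhat_NNR"]], state[["C_NO2"]],
                                   params$regulator),
         E_NAR = enzyme_derivative(state[["E_NAR"]], act$f_act_nar,
                                   state[["B"]], params$expression),
         E_NIR = enzyme_derivative(state[["E_NIR"]], act$f_act_nir,
                                   state[["B"]], params$expression))
  check_finite_derivs(d[STATE_NAMES_ENZYME])
}

#' Right-hand side of the Monod-type model
#'
#' As [rhs_enzyme_model()] but without regulator or enzyme states; reduction
#' capacities are proportional to cell density, `r_max = numax * B`.
#'
#' @inheritParams rhs_enzyme_model
#' @return named numeric vector of derivatives.
#' @export
rhs_monod_model <- function(state, params, reactor) {
  kp <- params$kinetics
  r_O2 <- respiration_rate(state[["B"]], state[["C_O2"]], kp)
  r_NO3 <- reduction_rate(state[["C_NO3"]], state[["C_O2"]],
                          kp$numax_NAR * state[["B"]], kp$K_NO3, kp$Ireac_NAR)
  r_NO2 <- reduction_rate(state[["C_NO2"]], state[["C_O2"]],
                          kp$numax_NIR * state[["B"]], kp$K_NO2, kp$Ireac_NIR)
  check_finite_derivs(
    core_solute_derivs(state, r_O2, r_NO3, r_NO2, params, reactor)[STATE_NAMES_CORE]
  )
}

#' Right-hand side of the simplified transcription model
#'
#' Enzyme-based dynamics with promoter activities computed directly from the
#' current concentrations ([activities_simplified()]); transcription responds
#' instantaneously to the signaling molecules (no regulator lag), enzymes
#' still carry their own dynamics.
#'
#' @inheritParams rhs_enzyme_model
#' @return named numeric vector of derivatives.
#' @export
rhs_simplified_model <- function(state, params, reactor) {
  kp <- params$kinetics
  act <- activities_simplified(state[["C_O2"]], state[["C_NO3"]],
                               state[["C_NO2"]], params$regulator)
  r_O2 <- respiration_rate(state[["B"]], state[["C_O2"]], kp)
  r_NO3 <- reduction_rate(state[["C_NO3"]], state[["C_O2"]],
                          rmax_enzyme(kp$kmax_NAR, state[["E_NAR"]]),
                          kp$K_NO3, kp$Ireac_NAR)
  r_NO2 <- reduction_rate(state[["C_NO2"]], state[["C_O2"]],
                          rmax_enzyme(kp$kmax_NIR, state[["E_NIR"]]),
                          kp$K_NO2, kp$Ireac_NIR)
  d <- c(core_solute_derivs(state, r_O2, r_NO3, r_NO2, params, reactor),
         E_NAR = enzyme_derivative(state[["E_NAR"]], act$f_act_nar,
                                   state[["B"]], params$expression),
         E_NIR = enzyme_derivative(state[["E_NIR"]], act$f_act_nir,
                                   state[["B"]], params$expression))
  check_finite_derivs(d[STATE_NAMES_SIMPLIFIED])
}
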