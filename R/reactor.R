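#' Initial model state
#'
#' @param C_O2,C_NO3,C_NO2,C_N2 aqueous concentrations \[M\].
#' @param G_O2,G_N2 headspace concentrations \[mol per liter of headspace\].
#' @param B cell density \[cells/L\].
#' @param X_NarR,Xhat_NNR initial active regulator fractions.
#' @param E_NAR,E_NIR initial enzyme concentrations \[enzymes/L\].
#' @return named numeric vector in the canonical state layout.
#' @export
model_state <- function(C_O2 = 2.5e-4, C_NO3 = 2e-3, C_NO2 = 0, C_N2 = 0,
                        G_O2 = 8e-3, G_N2 = 0, B = 1e11,
                        X_NarR = 0, Xhat_NNR = 0, E_NAR = 0, E_NIR = 0) {
  s <- c(C_O2 = C_O2, C_NO3 = C_NO3, C_NO2 = C_NO2, C_N2 = C_N2,
         G_O2 = G_O2, G_N2 = G_N2, B = B,
         X_NarR = X_NarR, Xhat_NNR = Xhat_NNR, E_NAR = E_NAR, E_NIR = E_NIR)
  stopifnot_nonneg(state = s)
  if (X_NarR > 1 || Xhat_NNR > 1) {
    stop("regulator fractions must lie in [0, 1]", call. = FALSE)
  }
  s
}

#' Batch-reactor configuration
#'
#' Phase volumes, gas-liquid exchange coefficients, the headspace sampling
#' schedule and the initial state. Gas exchange follows a linear driving
#' force toward Henry's-law equilibrium; each sampling event removes
#' `V_sample` liters of headspace and replaces them with `replacement_gas`
#' (inert by default).
#'
#' @param V_liquid,V_gas phase volumes \[L\].
#' @param kLa_O2,kLa_N2 volumetric mass-transfer coefficients \[1/s\].
#' @param H_O2,H_N2 dimensionless Henry constants (gas/aqueous concentration
#'   ratio at equilibrium).
#' @param sampling_times ordered headspace sampling times \[hours\].
#' @param V_sample headspace volume removed per sampling \[L\].
#' @param replacement_gas named vector `c(G_O2=, G_N2=)` \[mol/L headspace\]
#'   of the gas replacing the sampled volume.
#' @param initial_state a [model_state()] vector.
#' @return object of class `reactor_setup`.
#' @export
reactor_setup <- function(V_liquid = 0.25, V_gas = 0.1,
                          kLa_O2 = 1e-3, kLa_N2 = 1e-3,
                          H_O2 = 32, H_N2 = 62,
                          sampling_times = seq(1, 49, by = 1),
                          V_sample = 0.002,
                          replacement_gas = c(G_O2 = 0, G_N2 = 0),
                          initial_state = model_state()) {
  stopifnot_positive(V_liquid = V_liquid, V_gas = V_gas,
                     kLa_O2 = kLa_O2, kLa_N2 = kLa_N2,
                     H_O2 = H_O2, H_N2 = H_N2)
  stopifnot_nonneg(V_sample = V_sample, sampling_times = sampling_times)
  if (length(sampling_times) && any(diff(sampling_times) <= 0)) {
    stop("sampling_times must be strictly increasing", call. = FALSE)
  }
  if (V_sample >= V_gas) stop("V_sample must be smaller than V_gas", call. = FALSE)
  stopifnot(all(c("G_O2", "G_N2") %in% names(replacement_gas)))
  structure(list(V_liquid = V_liquid, V_gas = V_gas,
                 kLa_O2 = kLa_O2, kLa_N2 = kLa_N2, H_O2 = H_O2, H_N2 = H_N2,
                 sampling_times = sampling_times, V_sample = V_sample,
                 replacement_gas = replacement_gas,
                 initial_state = initial_state),
            class = "reactor_setup")
}

#' Reference reactor configuration
#'
#' The default batch setup the synthetic experiment emulates: 0.25 L of
#' air-saturated medium (2.5e-4 M O2) with 2 mM nitrate under a 0.1 L
#' headspace initially at Henry equilibrium with the liquid for O2 and free
#' of N2, hourly headspace sampling of 2 mL replaced by inert gas.
#'
#' @param ... overrides passed to [reactor_setup()].
#' @return a `reactor_setup` object.
#' @export
reference_setup <- function(...) {
  args <- list(...)
  if (is.null(args$initial_state)) {
    args$initial_state <- model_state(C_O2 = 2.5e-4, G_O2 = 32 * 2.5e-4)
  }
  do.call(reactor_setup, args)
}

#' Gas-liquid mass-transfer rate (aqueous basis)
#'
#' Linear driving force toward Henry equilibrium:
#' `r_tr = kLa * (C_gas / H - C_aq)` \[mol/(L liquid s)\]. The paired
#' headspace derivative is `-(V_liquid/V_gas) * r_tr`, so total moles are
#' conserved by transfer.
#'
#' @param C_aq aqueous concentration \[M\].
#' @param C_gas headspace concentration \[mol/L headspace\].
#' @param kLa volumetric mass-transfer coefficient \[1/s\].
#' @param H dimensionless Henry constant (gas/aqueous at equilibrium).
#' @return transfer rate into the liquid \[mol/(L s)\].
#' @export
gas_transfer_rate <- function(C_aq, C_gas, kLa, H) {
  kLa * (C_gas / H - C_aq)
}

#' Apply one headspace sampling-dilution event
#'
#' Each gas-phase concentration is mixed with the replacement gas:
#' `G <- G * (1 - V_sample/V_gas) + (V_sample/V_gas) * G_replacement`.
#' Aqueous state, biomass, regulators and enzymes are unchanged.
#'
#' @param state named state vector.
#' @param setup a [reactor_setup()] object.
#' @return the state after the event.
#' @export
apply_sampling_event <- function(state, setup) {
  frac <- setup$V_sample / setup$V_gas
  for (g in c("G_O2", "G_N2")) {
    if (g %in% names(state)) {
      state[[g]] <- state[[g]] * (1 - frac) + frac * setup$replacement_gas[[g]]
    }
  }
  state
}
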