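# Shared fixtures: reference inputs, a coarse reference trajectory and the
# (expensive) synthetic-recovery runs, each computed once per test session.

ref_params <- reference_parameters()
ref_setup <- reference_setup()

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

reference_trajectory <- function(by = 0.25) {
  cached(paste0("traj", by),
         simulate_batch("enzyme", ref_params, ref_setup,
                        t_grid = seq(0, 50, by = by)))
}

# closed liquid-only system: negligible gas exchange, no sampling events
closed_setup <- function(...) {
  reactor_setup(kLa_O2 = 1e-30, kLa_N2 = 1e-30, sampling_times = numeric(0),
                ...)
}

random_state <- function(rng_seed) {
  set.seed(rng_seed)
  model_state(
    C_O2 = runif(1, 0, 3e-4), C_NO3 = runif(1, 0, 2e-3),
    C_NO2 = runif(1, 0, 2e-3), C_N2 = runif(1, 0, 1e-3),
    G_O2 = runif(1, 0, 9e-3), G_N2 = runif(1, 0, 2e-3),
    B = runif(1, 5e10, 3e11),
    X_NarR = runif(1), Xhat_NNR = runif(1),
    E_NAR = runif(1, 0, 2e14), E_NIR = runif(1, 0, 2e14)
  )
}

# Monod-model synthetic-data recovery (6 free parameters); ~5 min
monod_recovery <- function() {
  cached("monod_recovery", {
    obs <- generate_experiment(ref_params, ref_setup, noise_config(),
                               model = "monod", seed = 7)
    free6 <- c("numax_NAR", "numax_NIR", "K_NO2", "nufix_O2", "K_O2", "Y_O2")
    post <- build_posterior("monod", obs, ref_params, ref_setup, free = free6)
    draws <- sample_posterior(post, n_chains = 4, n_draws = 1000,
                              n_warmup = 1000, thin = 2, seed = 11)
    list(post = post, draws = draws)
  })
}

# reduced enzyme-based recovery (4 free parameters); ~2 min
enzyme_recovery <- function() {
  cached("enzyme_recovery", {
    obs <- generate_experiment(ref_params, ref_setup, noise_config(),
                               model = "enzyme", seed = 21)
    free4 <- c("Y_O2", "kmax_NIR", "K_NO2", "t_half_E_h")
    post <- build_posterior("enzyme", obs, ref_params, ref_setup, free = free4)
    draws <- sample_posterior(post, n_chains = 2, n_draws = 600,
                              n_warmup = 600, thin = 2, seed = 31)
    list(post = post, draws = draws)
  })
}
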