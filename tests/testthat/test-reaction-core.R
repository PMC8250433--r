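rp <- ref_params$regulator
ep <- ref_params$expression
kp <- ref_params$kinetics

test_that("regulator derivatives: limits, rejection, analytic fixed points", {
  # activation term vanishes at X = 1; pure decay remains
  expect_equal(narr_derivative(1, 5e-3, 1e-3, rp), -rp$kdec_NarR)
  expect_equal(narr_derivative(0, 0, 0, rp), 0)
  expect_equal(nnr_derivative(1, 0, rp), -rp$kdec_NNR)
  expect_equal(nnr_derivative(0, 0, rp), 0)
  expect_error(narr_derivative(1.2, 0, 0, rp), "\\[0, 1\\]")
  expect_error(narr_derivative(0.5, -1e-3, 0, rp), "non-negative")

  # analytic steady state X* = aC/(aC + kdec) against long-time integration
  C <- 7e-4
  xstar_narr <- rp$a_NarR_NO3 * C / (rp$a_NarR_NO3 * C + rp$kdec_NarR)
  xstar_nnr <- rp$a_NNR * C / (rp$a_NNR * C + rp$kdec_NNR)
  long <- deSolve::ode(
    y = c(xn = 0, xh = 0), times = c(0, 5e6),
    func = function(t, y, p) list(c(narr_derivative(y[1], C, 0, rp),
                                    nnr_derivative(y[2], C, rp))),
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  expect_equal(unname(long[2, "xn"]), xstar_narr, tolerance = 1e-7)
  expect_equal(unname(long[2, "xh"]), xstar_nnr, tolerance = 1e-7)
})

test_that("Hill inactivation of FnrP and NNR", {
  expect_equal(fnrp_active(0, rp), 1)
  expect_equal(fnrp_active(rp$I_FnrP, rp), 0.5)
  rp2 <- regulator_params(1, 1, 1e-4, I_FnrP = 1e-6, p = 2, a_NNR = 1,
                          kdec_NNR = 1e-4, I_NNR = 1e-6, q = 2,
                          K_FnrP = 0.1, K_NarR = 0.1, K_NNR = 0.1)
  expect_equal(fnrp_active(10e-6, rp2), 1 / 101)
  expect_equal(nnr_active(0.8, 0, rp), 0.8)
  expect_equal(nnr_active(0.8, rp$I_NNR, rp), 0.4)
  expect_equal(nnr_active(0, 1e-9, rp), 0)
})

test_that("promoter activities: zeros, half-saturation symmetry, saturation", {
  expect_equal(promoter_activity_nar(0, 0.5, rp), 0)
  expect_equal(promoter_activity_nar(0.5, 0, rp), 0)
  # both activators at their half-saturation constant: all four binding
  # polynomial terms equal 1
  expect_equal(promoter_activity_nar(rp$K_FnrP, rp$K_NarR, rp), 0.25)
  expect_gt(promoter_activity_nar(1e6 * rp$K_FnrP, 1e6 * rp$K_NarR, rp), 0.999)
  expect_equal(promoter_activity_nir(0, rp), 0)
  expect_equal(promoter_activity_nir(rp$K_NNR, rp), 0.5)
  expect_gt(promoter_activity_nir(1e6 * rp$K_NNR, rp), 0.999)
})

test_that("transcript quasi-steady state is beta_T * f_act * B", {
  expect_equal(transcript_qss(1, 2e11, ep$beta_T_nar), ep$beta_T_nar * 2e11)
  expect_equal(transcript_qss(0.7, 0, ep$beta_T_nar), 0)
  expect_equal(transcript_qss(0.5, 1e9, 100), 5e10)
})

test_that("enzyme pool relaxes exponentially to its quasi-steady state", {
  B <- 2e11; f <- 0.6
  Eqss <- ep$beta_E * f * B
  expect_equal(enzyme_derivative(Eqss, f, B, ep), 0)
  expect_equal(enzyme_derivative(3e13, 0, B, ep), -ep$kdec_E * 3e13)

  # closed form E(t) = Eqss + (E0 - Eqss) exp(-kdec_E t) vs integration
  E0 <- 1e13
  tt <- c(0, 3600, 10800, 36000)
  sol <- deSolve::ode(y = c(E = E0), times = tt,
                      func = function(t, y, p) list(enzyme_derivative(y, f, B, ep)),
                      parms = NULL, rtol = 1e-10, atol = 1e-4)
  expect_equal(unname(sol[, "E"]), Eqss + (E0 - Eqss) * exp(-ep$kdec_E * tt),
               tolerance = 1e-8)
  # half the gap closes in one half-life
  t_half <- log(2) / ep$kdec_E
  E_half <- Eqss + (E0 - Eqss) * exp(-ep$kdec_E * t_half)
  expect_equal(E_half - Eqss, (E0 - Eqss) / 2)
})

test_that("reduction and respiration rate laws: limits and monotonicity", {
  expect_equal(reduction_rate(1e6, 0, 2e-8, kp$K_NO3, kp$Ireac_NAR), 2e-8,
               tolerance = 1e-9)
  expect_equal(reduction_rate(kp$K_NO3, kp$Ireac_NAR, 2e-8, kp$K_NO3,
                              kp$Ireac_NAR), 2e-8 / 4)
  expect_equal(reduction_rate(0, 0, 2e-8, kp$K_NO3, kp$Ireac_NAR), 0)

  # monotone non-decreasing in substrate, non-increasing in oxygen
  set.seed(4)
  Cs <- sort(runif(40, 0, 3e-3)); Os <- sort(runif(40, 0, 3e-4))
  r_sub <- reduction_rate(Cs, 1e-5, 1e-8, kp$K_NO2, kp$Ireac_NIR)
  r_o2 <- reduction_rate(1e-3, Os, 1e-8, kp$K_NO2, kp$Ireac_NIR)
  expect_true(all(diff(r_sub) >= 0))
  expect_true(all(diff(r_o2) <= 0))

  expect_equal(respiration_rate(2e11, 0, kp), 0)
  expect_equal(respiration_rate(2e11, kp$K_O2, kp), kp$numax_O2 * 2e11 / 2)
  # definition of the reparameterization: rate at C_fix equals nufix_O2 * B
  expect_equal(respiration_rate(2e11, kp$C_fix, kp), kp$nufix_O2 * 2e11)
})

test_that("growth couples to respiration with the 2/7 energy stoichiometry", {
  expect_equal(growth_rate(0, kp), 0)
  kp1 <- kinetic_params(1, 1, 1e-19, 1e-19, 1e-5, 1e-5, 1e-6, 1e-6,
                        1e-19, 1e-5, Y_O2 = 1e13)
  expect_equal(growth_rate(7e-10, kp1), 2e3)
  expect_equal(growth_rate(2 * 7e-10, kp1), 2 * growth_rate(7e-10, kp1))
})

test_that("assembled right-hand sides compose the standalone rate laws", {
  for (seed in c(11, 23, 57)) {
    st <- random_state(seed)
    d <- rhs_enzyme_model(st, ref_params, ref_setup)

    r_O2 <- respiration_rate(st[["B"]], st[["C_O2"]], kp)
    rmax_nar <- rmax_enzyme(kp$kmax_NAR, st[["E_NAR"]])
    r_NO3 <- reduction_rate(st[["C_NO3"]], st[["C_O2"]], rmax_nar,
                            kp$K_NO3, kp$Ireac_NAR)
    r_NO2 <- reduction_rate(st[["C_NO2"]], st[["C_O2"]],
                            rmax_enzyme(kp$kmax_NIR, st[["E_NIR"]]),
                            kp$K_NO2, kp$Ireac_NIR)
    tr_O2 <- gas_transfer_rate(st[["C_O2"]], st[["G_O2"]],
                               ref_setup$kLa_O2, ref_setup$H_O2)
    expect_equal(d[["C_NO3"]], -r_NO3)
    expect_equal(d[["C_NO2"]], r_NO3 - r_NO2)
    expect_equal(d[["C_O2"]], -r_O2 + tr_O2)
    expect_equal(d[["B"]], growth_rate(r_O2, kp))
    expect_equal(d[["X_NarR"]],
                 narr_derivative(st[["X_NarR"]], st[["C_NO3"]], st[["C_NO2"]], rp))
    act <- activities_simplified(st[["C_O2"]], st[["C_NO3"]], st[["C_NO2"]], rp)
    ds <- rhs_simplified_model(st, ref_params, ref_setup)
    expect_equal(ds[["E_NAR"]],
                 enzyme_derivative(st[["E_NAR"]], act$f_act_nar, st[["B"]], ep))
  }
})

test_that("zero rate parameters give an identically zero derivative", {
  tiny <- 1e-30
  p0 <- parameter_set(
    regulator = regulator_params(tiny, tiny, tiny, 1e-6, 1, tiny, tiny, 1e-6,
                                 1, 0.1, 0.1, 0.1),
    expression = expression_params(1, 1, beta_E = 1125, t_half_E_h = 1e25),
    kinetics = kinetic_params(tiny, tiny, tiny, tiny, 1e-5, 1e-5, 1e-6, 1e-6,
                              tiny, 1e-5, tiny)
  )
  quiet <- reactor_setup(kLa_O2 = 1e-30, kLa_N2 = 1e-30,
                         sampling_times = numeric(0),
                         initial_state = model_state(G_O2 = 32 * 2.5e-4))
  d <- rhs_enzyme_model(quiet$initial_state, p0, quiet)
  expect_true(all(abs(d) < 1e-15))
})

test_that("nitrogen is conserved by the assembled derivatives in a closed system", {
  cs <- closed_setup()
  for (seed in c(3, 19, 42, 77)) {
    st <- random_state(seed)
    for (f in list(rhs_enzyme_model, rhs_monod_model, rhs_simplified_model)) {
      d <- f(st, ref_params, cs)
      dN <- d[["C_NO3"]] + d[["C_NO2"]] + 2 * d[["C_N2"]]
      expect_lt(abs(dN), 1e-9 * max(abs(d[["C_NO3"]]), 1e-30))
    }
  }
})

test_that("simplified model responds to nitrite instantaneously, regulator model lags", {
  # step change in nitrite changes the simplified activity with no lag state
  a0 <- activities_simplified(0, 1e-3, 0, rp)
  a1 <- activities_simplified(0, 1e-3, 1e-3, rp)
  expect_equal(a0$f_act_nir, 0)
  expect_gt(a1$f_act_nir, 0.5)
  # anoxic, saturating substrate: nar activity approaches 1
  expect_gt(activities_simplified(0, 1, 1, rp)$f_act_nar, 0.999)
  # high oxygen shuts both down
  ahi <- activities_simplified(1e-2, 1e-3, 1e-3, rp)
  expect_lt(ahi$f_act_nar, 1e-4)
  expect_lt(ahi$f_act_nir, 1e-6)

  # the transcription-factor model sees the same step only through the slow
  # regulator state: immediately after the step X_NNR is still ~0
  st <- model_state(C_O2 = 0, C_NO3 = 1e-3, C_NO2 = 1e-3, Xhat_NNR = 0)
  d <- rhs_enzyme_model(st, ref_params, ref_setup)
  expect_gt(d[["Xhat_NNR"]], 0)           # activation has begun...
  expect_equal(nnr_active(0, 0, rp), 0)   # ...but activity is still zero
})

test_that("expression parameter identities hold exactly", {
  for (bT in c(0.5, 3, 40)) {
    e <- expression_params(beta_T_nar = bT, beta_T_nir = 2 * bT,
                           t_half_E_h = 4.2, t_half_T_min = 2.5)
    expect_equal(e$k_translation_nar, e$kdec_E * e$beta_E / bT,
                 tolerance = 1e-12)
    expect_equal(e$alpha_nar, bT * e$kdec_T, tolerance = 1e-12)
    # the quasi-steady enzyme level at full activation is beta_E per cell
    expect_equal(e$k_translation_nar * bT / e$kdec_E, e$beta_E,
                 tolerance = 1e-12)
  }
  expect_error(expression_params(-1, 1), "positive")
  expect_error(regulator_params(1, 1, 1e-4, 1e-6, p = 0.5, 1, 1e-4, 1e-6,
                                2, 0.1, 0.1, 0.1), "Hill")
})
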