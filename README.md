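# denitrodyn

Does it pay to resolve gene expression when modeling denitrification rates?
`denitrodyn` implements two competing formulations of a *Paracoccus
denitrificans* batch experiment (aerobic medium, 5 mM succinate, 2 mM
nitrate, sealed headspace) and the Bayesian machinery to calibrate and
compare them:

* an **enzyme-based model** that simulates transcription-factor activation
  (FnrP, NarR, NNR), *narG*/*nirS* transcription, enzyme production and
  decay, and couples reduction rates to enzyme pools, and
* a classical **Monod-type model** with rates proportional to cell density.

It is written for biogeochemical modelers and molecular microbial ecologists
who want to test, on controlled or synthetic data, whether transcript
abundances can serve as quantitative rate proxies — and to reproduce the
characteristic negative result: the transcript–rate relation is strongly
non-linear and hysteretic.

## The model in brief

Regulator dynamics (fractions of active transcription factor):

    dX_NarR/dt = (a_NO3 C_NO3 + a_NO2 C_NO2)(1 − X_NarR) − kdec_NarR X_NarR
    X_FnrP     = I_FnrP^p / (I_FnrP^p + C_O2^p)                (equilibrium)
    dX̂_NNR/dt  = a_NNR C_NO2 (1 − X̂_NNR) − kdec_NNR X̂_NNR
    X_NNR      = I_NNR^q / (I_NNR^q + C_O2^q) · X̂_NNR

Promoter activities f_act gate transcription; transcripts are at
quasi-steady state, T_qss = β_T · f_act · B, and enzymes relax toward
E_qss = β_E · f_act · B with rate kdec_E (translation is tied to decay via
k_translation = kdec_E β_E / β_T, with β_E fixed at 1125 enzymes/cell since
only the product kmax·E is identifiable). Reduction steps follow
Michaelis–Menten kinetics with oxygen inhibition,

    r_j = r_max · C_j/(C_j + K_j) · I_reac/(I_reac + C_O2),

with r_max = kmax·E/N_A (enzyme-based) or ν_max·B (Monod). Aerobic
respiration is a Monod rate law, growth couples to it through the balanced
energy reaction 2 succinate + 7 O₂ → 8 CO₂ + 6 H₂O, and the reactor adds
Henry's-law gas exchange plus discrete headspace-sampling dilution events.
Calibration uses a Box–Cox Student-t likelihood (ν = 10) with a composite
data + model error scale, log-normal/uniform priors over 14 (Monod) or 32
(enzyme-based) free parameters, an adaptive-Metropolis sampler, and
rank-normalized split R-hat diagnostics.

## Worked example

```r
library(denitrodyn)

params <- reference_parameters()
traj <- simulate_batch("enzyme", params, reference_setup(),
                       t_grid = seq(0, 50, 0.25))
traj
#> <denit_trajectory> model=enzyme, 201 time points over [0, 50] h

df <- as.data.frame(traj)
max(df$C_NO2) * 1e3                      # peak nitrite, mM
#> 1.99
median(df$T_nar_per_cell[df$C_O2 > 0.5 * df$C_O2[1]])
#> 0.012                                  # oxic-phase narG baseline per cell

rel <- rate_relation(traj, predictor = "transcript", reaction = "NIR")
hysteresis_index(rel)
#> 0.48
qss_comparison(traj)$max_ratio[["NIR"]]
#> 5.4
```

Read: the culture respires oxygen for ~16 h (narG transcripts idling at
1e-2 per cell), converts all 2 mM nitrate to nitrite — hence the nitrite
peak equals the initial nitrate level — then reduces nitrite to N₂. The
transcript–rate relation for nitrite reduction traces an open loop (area
0.48 on normalized axes): transcripts peak long before rates do, so no
single-valued function maps one to the other. Transient enzyme pools stay
up to ~5x below their quasi-steady-state levels, which is why a QSS enzyme
approximation would fail here.

Synthetic experiments and calibration:

```r
obs <- generate_experiment(params, reference_setup(), noise_config(),
                           model = "monod", seed = 7)
post <- build_posterior("monod", obs, params,
                        free = c("numax_NAR", "numax_NIR", "K_NO2",
                                 "nufix_O2", "K_O2", "Y_O2"))
draws <- sample_posterior(post, n_chains = 4, n_draws = 1000,
                          n_warmup = 1000, thin = 2, seed = 11)
draws$rhat$max          # ~1.02
posterior_correlations(draws)
```

A thin CLI wraps the same functions:
`Rscript inst/cli/denit.R {simulate|synthesize|calibrate|analyze} --seed S ...`.

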