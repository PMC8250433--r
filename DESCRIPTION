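Package: denitrodyn
Title: Enzyme-Based and Monod-Type Models of Batch Denitrification with
    Bayesian Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates batch-reactor denitrification by Paracoccus
    denitrificans with two alternative kinetic formulations: an enzyme-based
    model that resolves transcription-factor activation, functional-gene
    transcription (narG, nirS), enzyme production and decay, and a classical
    Monod-type model. Includes headspace gas exchange, discrete gas-sampling
    dilution events, stiff log-state ODE integration, a Box-Cox Student-t
    observation model with Bayesian parameter estimation via adaptive MCMC,
    rank-normalized split R-hat diagnostics, a synthetic-experiment
    generator, and post-hoc analyses of transcript-rate hysteresis and the
    enzyme quasi-steady-state assumption.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
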