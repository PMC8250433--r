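#' @keywords internal
"_PACKAGE"

#' @useDynLib denitrodyn, .registration = TRUE
NULL

## Avogadro constant [molecules mol^-1]; converts per-liter enzyme counts to
## molar amounts in the enzyme-based rate law.
N_AVOGADRO <- 6.02214076e23

## Stoichiometric coefficients of the aerobic energy reaction
## 2 succinate + 7 O2 -> 8 CO2 + 6 H2O; immutable by construction.
N_SUCC <- 2
N_O2 <- 7

SECONDS_PER_HOUR <- 3600

## Canonical observed variables and their file units.
OBS_VARIABLES <- c(
  O2_aqueous   = "mM",
  NO2          = "mM",
  N2_headspace = "mM",
  cell_density = "cells_per_L",
  narG_per_cell = "transcripts_per_cell",
  nirS_per_cell = "transcripts_per_cell"
)

## State layout shared with the compiled right-hand sides (src/denit_rhs.c).
STATE_NAMES_CORE <- c("C_O2", "C_NO3", "C_NO2", "C_N2", "G_O2", "G_N2", "B")
STATE_NAMES_ENZYME <- c(STATE_NAMES_CORE, "X_NarR", "Xhat_NNR", "E_NAR", "E_NIR")
STATE_NAMES_SIMPLIFIED <- c(STATE_NAMES_CORE, "E_NAR", "E_NIR")

MODEL_CHOICES <- c("enzyme", "monod", "simplified")

state_names_for <- function(model) {
  switch(match.arg(model, MODEL_CHOICES),
    enzyme = STATE_NAMES_ENZYME,
    monod = STATE_NAMES_CORE,
    simplified = STATE_NAMES_SIMPLIFIED
  )
}

stopifnot_positive <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a single strictly positive number", nm[i]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

stopifnot_nonneg <- function(...) {
  vals <- list(...)
  nm <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("'%s' must be finite and non-negative", nm[i]), call. = FALSE)
    }
  }
  invisible(TRUE)
}
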