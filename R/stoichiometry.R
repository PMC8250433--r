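## Element bookkeeping for the three redox reactions driving the batch system:
##   nitrate reduction:  7 NO3- + C4H6O4 -> 7 NO2- + 4 CO2 + 3 H2O
##   nitrite reduction: 14 NO2- + 14 H+ + 3 C4H6O4 -> 7 N2 + 12 CO2 + 16 H2O
##   aerobic respiration: 2 C4H6O4 + 7 O2 -> 8 CO2 + 6 H2O
## Growth is coupled to respiration only, so the 7:2 O2:succinate ratio of the
## energy reaction fixes the yield conversion in `growth_rate()`.

#' Parse a chemical formula into element counts
#'
#' Understands simple formulas such as `"C4H6O4"`, `"NO3-"` or `"H+"`.
#' Charge signs are tallied under the pseudo-element `"charge"`.
#'
#' @param formula a single formula string.
#' @return named numeric vector of element counts.
#' @keywords internal
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  charge <- 0
  body <- formula
  m <- regmatches(formula, regexpr("[+-]+$", formula))
  if (length(m) == 1L && nzchar(m)) {
    signs <- strsplit(m, "")[[1]]
    charge <- sum(ifelse(signs == "+", 1, -1))
    body <- sub("[+-]+$", "", formula)
  }
  tokens <- regmatches(body, gregexpr("[A-Z][a-z]?[0-9]*", body))[[1]]
  if (!nzchar(body) || nchar(paste(tokens, collapse = "")) != nchar(body)) {
    stop("cannot parse chemical formula: ", formula, call. = FALSE)
  }
  counts <- numeric(0)
  for (tok in tokens) {
    el <- regmatches(tok, regexpr("^[A-Z][a-z]?", tok))
    n <- sub("^[A-Z][a-z]?", "", tok)
    n <- if (nzchar(n)) as.numeric(n) else 1
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) + n
  }
  if (charge != 0) counts["charge"] <- charge
  counts
}

#' Check element and charge balance of a reaction
#'
#' @param lhs,rhs named numeric vectors of stoichiometric coefficients,
#'   names are chemical formulas (e.g. `c("C4H6O4" = 2, "O2" = 7)`).
#' @return `TRUE` invisibly if balanced; otherwise an error naming the
#'   unbalanced element.
#' @export
check_element_balance <- function(lhs, rhs) {
  tally <- function(side, sign) {
    out <- numeric(0)
    for (i in seq_along(side)) {
      counts <- parse_formula(names(side)[i]) * side[[i]] * sign
      for (el in names(counts)) {
        out[el] <- (if (el %in% names(out)) out[[el]] else 0) + counts[[el]]
      }
    }
    out
  }
  net <- tally(lhs, +1)
  for (el in names(tr <- tally(rhs, -1))) {
    net[el] <- (if (el %in% names(net)) net[[el]] else 0) + tr[[el]]
  }
  bad <- names(net)[abs(net) > 1e-9]
  if (length(bad)) {
    stop("reaction not balanced in: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Stoichiometry of the aerobic energy reaction used for growth coupling
#'
#' Verifies by element balance that the respiration reaction
#' 2 succinate + 7 O2 -> 8 CO2 + 6 H2O is consistent, and returns the
#' coefficients used throughout the package.
#'
#' @return list with `n_succ`, `n_O2`, and `O2_per_succinate` (= 7/2).
#' @export
respiration_stoichiometry <- function() {
  check_element_balance(
    c("C4H6O4" = N_SUCC, "O2" = N_O2),
    c("CO2" = 8, "H2O" = 6)
  )
  list(n_succ = N_SUCC, n_O2 = N_O2, O2_per_succinate = N_O2 / N_SUCC)
}

#' Stoichiometry of the two denitrification steps
#'
#' Element/charge-balance check of nitrate reduction to nitrite and nitrite
#' reduction to N2, both coupled to succinate oxidation. Also documents that
#' the electron donor is never limiting under the default experiment:
#' full reduction of 2 mM nitrate consumes (1/7)*2 + (3/14)*2 ~ 0.71 mM
#' succinate while 5 mM is supplied.
#'
#' @return list of the two reactions' coefficient vectors.
#' @export
denitrification_stoichiometry <- function() {
  nar <- list(lhs = c("NO3-" = 7, "C4H6O4" = 1),
              rhs = c("NO2-" = 7, "CO2" = 4, "H2O" = 3))
  nir <- list(lhs = c("NO2-" = 14, "H+" = 14, "C4H6O4" = 3),
              rhs = c("N2" = 7, "CO2" = 12, "H2O" = 16))
  check_element_balance(nar$lhs, nar$rhs)
  check_element_balance(nir$lhs, nir$rhs)
  list(nitrate_reduction = nar, nitrite_reduction = nir,
       succinate_per_mol_NO3 = 1 / 7 + 3 / 14)
}
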