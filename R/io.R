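## File formats: tidy-CSV observations and trajectories, YAML/JSON parameter
## files with fixed/free flags and priors, provenance records. Times in
## files are hours and concentrations mM (transcripts per cell, cells per
## liter); conversion to SI happens at the model boundary.

#' Read an observation set from tidy CSV
#'
#' Expects the header `variable, time_h, replicate, value, sd, unit`, checks
#' units against the canonical unit per variable, rejects negative values,
#' unknown variables and duplicated (variable, time, replicate) rows.
#'
#' @param path CSV file path.
#' @return a [observation_set()].
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("observation file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  observation_set(df)
}

#' Write an observation set to tidy CSV
#'
#' @param obs a `denit_obs` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  stopifnot(inherits(obs, "denit_obs"))
  df <- obs$data
  # 17 significant digits so numeric columns survive the round trip exactly
  for (col in c("time_h", "value", "sd")) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## trajectory state columns exported in file units
.traj_units <- c(C_O2 = "mM", C_NO3 = "mM", C_NO2 = "mM", C_N2 = "mM",
                 G_O2 = "mM", G_N2 = "mM", B = "cells_per_L",
                 X_NarR = "fraction", Xhat_NNR = "fraction",
                 E_NAR = "enzymes_per_L", E_NIR = "enzymes_per_L")

#' Export a trajectory as tidy CSV
#'
#' Long format with columns `time_h, variable, value, unit`; molar state
#' variables are converted to mM, derived series are appended in their
#' natural units.
#'
#' @param traj a `denit_trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  rows <- list()
  for (v in colnames(traj$states)) {
    unit <- .traj_units[[v]]
    val <- traj$states[, v]
    if (unit == "mM") val <- val * 1e3
    rows[[v]] <- data.frame(time_h = traj$time_h, variable = v,
                            value = val, unit = unit)
  }
  for (v in setdiff(names(traj$derived), "time_h")) {
    rows[[v]] <- data.frame(time_h = traj$time_h, variable = v,
                            value = traj$derived[[v]], unit = "derived")
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a parameter/prior configuration file
#'
#' YAML or JSON mapping of parameter name to `{value, fixed, prior: {dist,
#' arg1, arg2}, unit}`; entries are merged over the package defaults
#' ([reference_parameters()] values, [parameter_ledger()] priors). Marking a
#' default-free parameter `fixed: true` removes it from the estimation
#' ledger; a `prior` on a parameter marked fixed is an error, as is an
#' unknown parameter name.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file; `NULL` or a
#'   non-existent empty specification yields the pure defaults.
#' @param model `"enzyme"` or `"monod"`.
#' @return list with `params` (a `denit_params`), `ledger` (free-parameter
#'   prior table) and `n_free`.
#' @export
read_parameters <- function(path = NULL, model = c("enzyme", "monod")) {
  model <- match.arg(model)
  params <- reference_parameters()
  ledger <- parameter_ledger(model, params)
  spec <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
    spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(spec)) spec <- list()
  }
  known <- unique(c(ledger$name, names(unlist(unclass(params$regulator))),
                    "beta_T_nar", "beta_T_nir", "beta_E", "t_half_E_h",
                    "t_half_T_min",
                    names(params$kinetics), "b_O2", "b_NO2",
                    paste0("sigma_model_", names(OBS_VARIABLES))))
  vals <- c()
  for (nm in names(spec)) {
    if (!nm %in% known) stop("unknown parameter name: ", nm, call. = FALSE)
    entry <- spec[[nm]]
    if (!is.list(entry)) entry <- list(value = entry)
    fixed <- isTRUE(entry$fixed)
    if (fixed && !is.null(entry$prior)) {
      stop("parameter '", nm, "' is fixed but carries a prior", call. = FALSE)
    }
    if (!is.null(entry$value)) vals[nm] <- as.numeric(entry$value)
    if (fixed) {
      ledger <- ledger[ledger$name != nm, ]
    } else if (!is.null(entry$prior)) {
      pr <- entry$prior
      if (!nm %in% ledger$name) {
        ledger <- rbind(ledger, data.frame(
          name = nm, block = "user", default = as.numeric(entry$value %||% NA),
          dist = pr$dist, arg1 = as.numeric(pr$arg1), arg2 = as.numeric(pr$arg2)))
      } else {
        i <- match(nm, ledger$name)
        ledger$dist[i] <- pr$dist
        ledger$arg1[i] <- as.numeric(pr$arg1)
        ledger$arg2[i] <- as.numeric(pr$arg2)
      }
    }
  }
  if (length(vals)) {
    params <- update_parameters(params, vals)
    i <- match(names(vals), ledger$name)
    ok <- !is.na(i)
    ledger$default[i[ok]] <- vals[ok]
    ledger$arg1[i[ok]][ledger$dist[i[ok]] == "lognormal"] <-
      log(vals[ok][ledger$dist[i[ok]] == "lognormal"])
  }
  rownames(ledger) <- NULL
  list(params = params, ledger = ledger, n_free = nrow(ledger))
}

#' Write a parameter set (with its estimation ledger) to YAML
#'
#' @param params a `denit_params`.
#' @param ledger free-parameter table ([parameter_ledger()]).
#' @param path output `.yml` path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, ledger, path) {
  flat <- c(unclass(params$regulator),
            params$expression[c("beta_T_nar", "beta_T_nir", "beta_E",
                                "t_half_E_h", "t_half_T_min")],
            unclass(params$kinetics)[c("kmax_NAR", "kmax_NIR", "numax_NAR",
                                       "numax_NIR", "K_NO3", "K_NO2",
                                       "Ireac_NAR", "Ireac_NIR", "nufix_O2",
                                       "K_O2", "Y_O2", "C_fix")],
            list(b_O2 = params$error$b_O2, b_NO2 = params$error$b_NO2),
            stats::setNames(as.list(params$error$sigma_model),
                            paste0("sigma_model_", names(params$error$sigma_model))))
  out <- lapply(names(flat), function(nm) {
    i <- match(nm, ledger$name)
    e <- list(value = flat[[nm]], fixed = is.na(i))
    if (!is.na(i)) {
      e$prior <- list(dist = ledger$dist[i], arg1 = ledger$arg1[i],
                      arg2 = ledger$arg2[i])
    }
    e
  })
  names(out) <- names(flat)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Provenance record for a run
#'
#' Package version, seed and an MD5 digest of the configuration, to be
#' written alongside any output.
#'
#' @param config any serializable configuration object.
#' @param seed integer seed of the run.
#' @return list with `package`, `version`, `seed`, `config_md5`, `time`.
#' @export
provenance_record <- function(config, seed) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp)
  list(package = "denitrodyn",
       version = as.character(utils::packageVersion("denitrodyn")),
       seed = seed,
       config_md5 = unname(tools::md5sum(tmp)),
       time = format(Sys.time(), tz = "UTC"))
}
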