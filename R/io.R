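# CSV tables and run configurations.
#
# Dialect: comma-separated, UTF-8, "." decimal separator, header required;
# permil values are stored as plain numbers. Summary files round to 4
# decimals (the precision of the printed case-study tables); chain dumps keep
# full precision.

read_csv_quiet <- function(path) {
  if (!file.exists(path)) stop_spec("file not found: %s", path)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read a sources table
#'
#' Expected header: `name`, `mode`, then per signature `<label>_mean` plus
#' `<label>_sd` (point mode) or `<label>_halfrange` (range mode), optionally
#' `<label>_margin`. Mode-specific columns are enforced per row.
#'
#' @param path CSV file path.
#' @return A validated tibble of sources, ready for [iso_model()].
#' @export
read_sources <- function(path) {
  df <- read_csv_quiet(path)
  if (nrow(df) == 0) stop_spec("no sources defined in %s", path)
  if (!all(c("name", "mode") %in% names(df))) {
    stop_spec("%s must have 'name' and 'mode' columns", path)
  }
  sigs <- infer_signatures(df)
  if (length(sigs) == 0) {
    stop_spec("%s has no '<signature>_mean' columns", path)
  }
  for (j in seq_len(nrow(df))) {
    for (s in sigs) {
      sd_col <- paste0(s, "_sd")
      hr_col <- paste0(s, "_halfrange")
      sdv <- if (sd_col %in% names(df)) df[[sd_col]][j] else NA_real_
      hrv <- if (hr_col %in% names(df)) df[[hr_col]][j] else NA_real_
      if (df$mode[j] == "point") {
        if (!is.finite(sdv)) {
          stop_spec("row %d ('%s'): point mode needs column %s", j,
                    df$name[j], sd_col)
        }
        if (is.finite(hrv) && hrv != 0) {
          stop_spec("row %d ('%s'): point mode must leave %s empty", j,
                    df$name[j], hr_col)
        }
        if (sdv < 0) stop_spec("row %d: negative %s", j, sd_col)
      } else if (df$mode[j] == "range") {
        if (!is.finite(hrv)) {
          stop_spec("row %d ('%s'): range mode needs column %s", j,
                    df$name[j], hr_col)
        }
        if (is.finite(sdv) && sdv != 0) {
          stop_spec("row %d ('%s'): range mode must leave %s empty", j,
                    df$name[j], sd_col)
        }
        if (hrv < 0) stop_spec("row %d: negative %s", j, hr_col)
      } else {
        stop_spec("row %d: mode must be 'point' or 'range'", j)
      }
    }
  }
  if (anyDuplicated(df$name)) {
    stop_spec("duplicate source names in %s", path)
  }
  df
}

#' Read a samples table
#'
#' Expected header: `id`, then per signature `<label>` and `<label>_sd`.
#'
#' @param path CSV file path.
#' @param signatures Optional signature labels to cross-check against (e.g.
#'   from the sources table).
#' @return A tibble of measurements, one row per sample.
#' @export
read_samples <- function(path, signatures = NULL) {
  df <- read_csv_quiet(path)
  if (!"id" %in% names(df)) stop_spec("%s must have an 'id' column", path)
  sigs <- sub("_sd$", "", grep("_sd$", names(df), value = TRUE))
  if (length(sigs) == 0) {
    stop_spec("%s has no '<signature>_sd' columns", path)
  }
  missing_val <- setdiff(sigs, names(df))
  if (length(missing_val) > 0) {
    stop_spec("%s: value column(s) missing for %s", path,
              paste(missing_val, collapse = ", "))
  }
  if (!is.null(signatures) && !setequal(sigs, signatures)) {
    stop_spec("sample signatures (%s) do not match sources (%s)",
              paste(sort(sigs), collapse = ","),
              paste(sort(signatures), collapse = ","))
  }
  for (s in sigs) {
    if (any(!is.finite(df[[s]]))) stop_spec("%s: missing values in %s", path, s)
    sdv <- df[[paste0(s, "_sd")]]
    if (any(!is.finite(sdv)) || any(sdv <= 0)) {
      stop_spec("%s: %s_sd must be > 0 for every sample", path, s)
    }
  }
  df
}

#' Read an auxiliary-parameters table
#'
#' Expected header: `name`, optional `role`, then `<label>_mean` and
#' `<label>_sd` per signature.
#'
#' @param path CSV file path.
#' @return A tibble of auxiliary parameters.
#' @export
read_aux_params <- function(path) {
  df <- read_csv_quiet(path)
  if (!"name" %in% names(df)) stop_spec("%s must have a 'name' column", path)
  if (length(infer_signatures(df)) == 0) {
    stop_spec("%s has no '<signature>_mean' columns", path)
  }
  df
}

#' Write sources / samples / aux-parameter tables
#'
#' Plain CSV writers that round-trip with the corresponding readers.
#'
#' @param df Tibble as returned by the matching reader.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sources <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_sources
#' @export
write_samples <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_sources
#' @export
write_aux_params <- function(df, path) {
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration names the input tables and the model and sampler
#' settings:
#' \preformatted{
#' sources: sources.csv        # required
#' samples: samples.csv        # required
#' aux_params: aux_params.csv  # optional
#' equation: rayleigh          # builtin name or expression string
#' aux_vars: [r]               # optional; or list of {name, lo, hi}
#' equil_value: 8.6            # optional (nitrite builtin)
#' margin_mode: spread         # optional: spread | sigma
#' sampler:                    # optional overrides
#'   chain_length: 10000
#'   burn_in: 1000
#'   max_iterations: 2000000
#'   seed: 1
#'   method: threshold
#'   likelihood_mode: auto
#' output_dir: out
#' plots: false
#' }
#' Relative paths are resolved against the configuration file's directory.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file.
#' @return A named list with resolved paths and defaults filled in.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_spec("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (field in c("sources", "samples")) {
    if (is.null(cfg[[field]])) {
      stop_spec("config %s is missing required field '%s'", path, field)
    }
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (!grepl("^(/|[A-Za-z]:)", p)) file.path(base, p) else p
  }
  cfg$sources <- resolve(cfg$sources)
  cfg$samples <- resolve(cfg$samples)
  cfg$aux_params <- resolve(cfg$aux_params)
  defaults <- list(equation = "mixing", equil_value = 8.6,
                   margin_mode = "spread", plots = FALSE,
                   output_dir = ".")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  sampler_defaults <- list(chain_length = 10000, burn_in = 1000,
                           max_iterations = 2e6, method = "threshold",
                           likelihood_mode = "auto")
  cfg$sampler <- utils::modifyList(sampler_defaults,
                                   as.list(cfg$sampler %||% list()))
  cfg$config_dir <- base
  cfg
}

#' Build the model and samples described by a run configuration
#'
#' @param cfg A configuration list from [read_run_config()].
#' @return A list with elements `model` (an [iso_model()]) and `samples`
#'   (tibble).
#' @export
build_run <- function(cfg) {
  sources <- read_sources(cfg$sources)
  aux <- if (!is.null(cfg$aux_params)) read_aux_params(cfg$aux_params) else NULL
  aux_vars <- cfg$aux_vars
  if (!is.null(aux_vars) && !is.character(aux_vars)) {
    aux_vars <- tibble::as_tibble(aux_vars)
  }
  model <- iso_model(sources, aux_params = aux, aux_vars = aux_vars,
                     equation = cfg$equation,
                     equil_value = cfg$equil_value,
                     margin_mode = cfg$margin_mode)
  samples <- read_samples(cfg$samples, signatures = model$signatures)
  list(model = model, samples = samples)
}

#' Validate a run configuration
#'
#' Reads the configuration and all referenced tables, building the model to
#' surface any inconsistency (missing columns, mismatched signature labels,
#' invalid modes) as a single actionable error.
#'
#' @param path Configuration file path.
#' @return `TRUE` invisibly on success; otherwise an error describing the
#'   problem.
#' @export
check_run_config <- function(path) {
  cfg <- read_run_config(path)
  build_run(cfg)
  invisible(TRUE)
}

round_df <- function(df, digits = 4) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric),
                                  ~ round(.x, digits)))
}

#' Export chain, summary, correlation and diagnostics files
#'
#' @param chain An `iso_chain` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_csv <- function(chain, path) {
  readr::write_csv(chain_entries(chain), path)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
write_summary_csv <- function(chain, path) {
  readr::write_csv(round_df(posterior_summary(chain)), path)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
write_correlation_csv <- function(chain, path) {
  cm <- correlation_matrix(chain)
  df <- tibble::as_tibble(round_df(as.data.frame(cm)))
  df <- dplyr::bind_cols(tibble::tibble(variable = rownames(cm)), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' @rdname write_chain_csv
#' @export
write_diagnostics_json <- function(chain, path) {
  diag <- list(
    sample = chain$measurement$id,
    run = as.list(glance.iso_chain(chain)),
    z_scores = z_scores(chain)
  )
  jsonlite::write_json(diag, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
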