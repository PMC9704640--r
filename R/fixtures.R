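# Packaged case studies and the synthetic scenario generator used for
# parameter-recovery testing.

cases_dir <- function() {
  system.file("extdata", "cases", package = "isomix", mustWork = TRUE)
}

#' Names of the packaged case studies
#'
#' @return Character vector of case names accepted by [load_case()].
#' @export
case_names <- function() {
  sort(list.dirs(cases_dir(), recursive = FALSE, full.names = FALSE))
}

# Build a sources tibble from a from/to ranges table.
sources_from_ranges <- function(ranges) {
  sigs <- unique(sub("_(from|to)$", "",
                     grep("_(from|to)$", names(ranges), value = TRUE)))
  out <- tibble::tibble(name = ranges$name, mode = "range")
  for (s in sigs) {
    from <- ranges[[paste0(s, "_from")]]
    to <- ranges[[paste0(s, "_to")]]
    out[[paste0(s, "_mean")]] <- (from + to) / 2
    out[[paste0(s, "_halfrange")]] <- (to - from) / 2
  }
  out
}

#' Load a packaged case study
#'
#' Each case bundles the printed input tables of a worked example: sources
#' (as points with sd or as uniform ranges, the latter stored verbatim as
#' from/to bounds), samples with analytical sd, auxiliary fractionation
#' parameters and the bound model equation.
#'
#' @param name One of [case_names()]: `1d_example1`, `1d_example2`,
#'   `2d_mixing`, `2d_fractionation`, `nitrate_case1`, `nitrate_case2`,
#'   `evaporation`, `nitrite`, `n2o`.
#' @return A list with `model` (an [iso_model()]), `samples` (tibble),
#'   `note` (description), `name`, and for some cases extra tables:
#'   `ranges` (sources as printed from/to bounds), `measured` (raw
#'   end-member measurements before recalculation), `truth` (constructed
#'   fractions of synthetic samples).
#' @export
load_case <- function(name) {
  avail <- case_names()
  if (!name %in% avail) {
    stop_spec("unknown case '%s'; available cases: %s", name,
              paste(avail, collapse = ", "))
  }
  dir <- file.path(cases_dir(), name)
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))

  extras <- list()
  if (!is.null(cfg$ranges)) {
    extras$ranges <- read_csv_quiet(file.path(dir, cfg$ranges))
    sources <- sources_from_ranges(extras$ranges)
  } else {
    sources <- read_sources(file.path(dir, cfg$sources))
  }
  aux <- if (!is.null(cfg$aux_params)) {
    read_aux_params(file.path(dir, cfg$aux_params))
  } else NULL
  model <- iso_model(sources, aux_params = aux, aux_vars = cfg$aux_vars,
                     equation = cfg$equation,
                     equil_value = cfg$equil_value %||% 8.6)
  samples <- read_samples(file.path(dir, cfg$samples),
                          signatures = model$signatures)
  for (extra in c("measured", "truth")) {
    p <- file.path(dir, paste0(extra, ".csv"))
    if (file.exists(p)) extras[[extra]] <- read_csv_quiet(p)
  }
  c(list(name = name, model = model, samples = samples,
         note = trimws(cfg$note %||% "")), extras)
}

#' Export a packaged case to a directory
#'
#' Copies the case's input files so they can be edited and re-run through
#' the command-line interface.
#'
#' @param name A [case_names()] entry.
#' @param dir Destination directory (created if needed).
#' @return The destination directory, invisibly.
#' @export
export_case <- function(name, dir) {
  if (!name %in% case_names()) {
    stop_spec("unknown case '%s'; available cases: %s", name,
              paste(case_names(), collapse = ", "))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  src <- file.path(cases_dir(), name)
  for (f in list.files(src)) {
    file.copy(file.path(src, f), file.path(dir, f), overwrite = TRUE)
  }
  invisible(dir)
}

#' Generate a synthetic scenario with known truth
#'
#' Forward-simulates a measurement from a randomly drawn (or supplied) model
#' configuration, for parameter-recovery experiments: source means are drawn
#' uniformly in `[-30, 30]` permil per signature (a typical span of natural
#' stable-isotope end-members), source spreads/sds uniformly in
#' `[0.5, 3]` permil, true fractions from a flat Dirichlet and process
#' variables uniformly within their bounds. The measurement is the exact
#' forward value (auxiliary parameters at their means) plus Gaussian noise
#' of sd `noise_sd`.
#'
#' @param n_signatures Number of isotope signatures (1-3).
#' @param m_sources Number of sources.
#' @param equation Builtin equation name.
#' @param true_f Optional true fraction vector (default: random).
#' @param true_r Optional true auxiliary-variable value(s).
#' @param noise_sd Measurement noise sd (permil); also used as the sample's
#'   analytical sd (floored at 0.05 permil for the likelihood).
#' @param seed RNG seed; scenarios are fully reproducible.
#' @param mode Source definition mode, `"range"` or `"point"`.
#' @param aux_param_sd Sd attached to the auxiliary parameter `A`/`E` when
#'   the equation needs one.
#' @return A list: `model`, `sample` (one-row tibble), `true_f`, `true_r`,
#'   `seed`.
#' @export
generate_scenario <- function(n_signatures = 2, m_sources = 3,
                              equation = "mixing", true_f = NULL,
                              true_r = NULL, noise_sd = 0.5, seed = 1,
                              mode = c("range", "point"),
                              aux_param_sd = 1) {
  mode <- match.arg(mode)
  stopifnot(n_signatures >= 1, n_signatures <= 3, m_sources >= 1,
            noise_sd >= 0)
  set.seed(seed)
  sigs <- paste0("I", seq_len(n_signatures))
  src_names <- paste0("S", seq_len(m_sources))

  sources <- tibble::tibble(name = src_names, mode = mode)
  for (s in sigs) {
    sources[[paste0(s, "_mean")]] <- stats::runif(m_sources, -30, 30)
    spread <- stats::runif(m_sources, 0.5, 3)
    if (mode == "range") {
      sources[[paste0(s, "_halfrange")]] <- spread
    } else {
      sources[[paste0(s, "_sd")]] <- spread
    }
  }

  eq <- get_builtin_equation(equation)
  aux <- NULL
  if (length(eq$param_slots) > 0) {
    aux <- tibble::tibble(name = setdiff(eq$param_slots, "mult"))
    for (s in sigs) {
      aux[[paste0(s, "_mean")]] <- stats::runif(nrow(aux), -10, -2)
      aux[[paste0(s, "_sd")]] <- aux_param_sd
    }
  }
  model <- iso_model(sources, aux_params = aux,
                     aux_vars = if (eq$n_vars > 0) "r" else NULL,
                     equation = equation)

  if (is.null(true_f)) true_f <- drop(rdirichlet(1, rep(1, m_sources)))
  check_simplex(true_f)
  if (eq$n_vars > 0 && is.null(true_r)) true_r <- stats::runif(1, 0.2, 0.95)
  true_r <- true_r %||% numeric()

  pred <- predict_mu(model, true_f, true_r)
  x <- pred$mu + stats::rnorm(n_signatures, 0, noise_sd)
  sample <- tibble::tibble(id = sprintf("scenario_%d", seed))
  for (i in seq_len(n_signatures)) {
    sample[[sigs[i]]] <- x[i]
    sample[[paste0(sigs[i], "_sd")]] <- max(noise_sd, 0.05)
  }
  list(model = model, sample = sample, true_f = true_f, true_r = true_r,
       seed = seed)
}

#' Truth-recovery report over synthetic scenarios
#'
#' Runs the sampler on each scenario and compares the posterior to the known
#' truth: per-variable bias of the posterior mean, RMSE, and the rate at
#' which the central 95% credible interval covers the true value.
#'
#' @param scenarios List of [generate_scenario()] results.
#' @param ... Passed to [run_chain()] (e.g. `chain_length`, `seed`).
#' @return A tibble with one row per (scenario, variable):
#'   `scenario`, `variable`, `truth`, `post_mean`, `ci95_lo`, `ci95_hi`,
#'   `covered`, `error`. Aggregate with [summarize_recovery()]. Sampler
#'   failures are recorded as `NA` rows, not raised.
#' @export
recovery_report <- function(scenarios, ...) {
  if (length(scenarios) == 0) {
    return(tibble::tibble(scenario = integer(), variable = character(),
                          truth = numeric(), post_mean = numeric(),
                          ci95_lo = numeric(), ci95_hi = numeric(),
                          covered = logical(), error = character()))
  }
  purrr::map_dfr(seq_along(scenarios), function(k) {
    sc <- scenarios[[k]]
    truth <- c(stats::setNames(sc$true_f,
                               paste0("f_", sc$model$source_names)),
               if (length(sc$true_r) > 0)
                 stats::setNames(sc$true_r,
                                 paste0("r_", sc$model$vars$name)))
    res <- tryCatch(run_chain(sc$model, sc$sample, ...), error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble::tibble(scenario = k, variable = names(truth),
                            truth = unname(truth), post_mean = NA_real_,
                            ci95_lo = NA_real_, ci95_hi = NA_real_,
                            covered = NA, error = conditionMessage(res)))
    }
    ps <- posterior_summary(res)
    ps <- ps[match(names(truth), ps$variable), ]
    tibble::tibble(scenario = k, variable = names(truth),
                   truth = unname(truth), post_mean = ps$mean,
                   ci95_lo = ps$ci95_lo, ci95_hi = ps$ci95_hi,
                   covered = truth >= ps$ci95_lo & truth <= ps$ci95_hi,
                   error = NA_character_)
  })
}

#' Aggregate a recovery report
#'
#' @param report A [recovery_report()] tibble.
#' @return Per-variable bias, RMSE and CI95 coverage rate.
#' @export
summarize_recovery <- function(report) {
  report |>
    dplyr::filter(is.na(.data$error)) |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias = mean(.data$post_mean - .data$truth),
      rmse = sqrt(mean((.data$post_mean - .data$truth)^2)),
      coverage = mean(.data$covered),
      .groups = "drop")
}
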