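# Model assembly: sources, auxiliary parameters/variables and an equation.

infer_signatures <- function(df, suffix = "_mean") {
  nms <- names(df)
  sub(suffix, "", nms[endsWith(nms, suffix)], fixed = TRUE)
}

sig_col <- function(df, sig, suffix) {
  col <- paste0(sig, suffix)
  if (col %in% names(df)) as.numeric(df[[col]]) else rep(NA_real_, nrow(df))
}

#' Assemble a mixing/fractionation model
#'
#' Builds the model object consumed by [run_chain()] and friends from tidy
#' tables of sources and auxiliary parameters.
#'
#' `sources` must have columns `name`, `mode` (`"point"` or `"range"`) and,
#' for every isotope signature label `<sig>`, a `<sig>_mean` column plus
#' either `<sig>_sd` (point mode: Gaussian sd) or `<sig>_halfrange` (range
#' mode: half-width of a uniform range). An optional `<sig>_margin` column
#' adds the analytical uncertainty of a range-mode source; by default it
#' widens the range (`margin_mode = "spread"`), alternatively it is added to
#' the Gaussian sd in quadrature (`margin_mode = "sigma"`).
#'
#' `aux_params` (optional) has columns `name`, optional `role`, and
#' `<sig>_mean` / `<sig>_sd` per signature. During sampling each parameter is
#' redrawn from its Gaussian at every proposal, so parameter uncertainty is
#' marginalised over. Built-in equations refer to parameters by name:
#' `A` (fractionation factor), `E` (equilibrium endpoint or open-system
#' factor), `D` (limiting evaporative enrichment), `B`/`C` (nitrite model),
#' `mult` (optional per-signature multiplier of the equilibrated fraction).
#'
#' `aux_vars` (optional) declares the process-progress variables sampled
#' uniformly within prior bounds: a character vector (bounds `[0, 1]`) or a
#' data frame with columns `name`, `lo`, `hi`. Built-ins need at most one,
#' conventionally called `r`; its meaning (residual, reduced, equilibrated or
#' evaporated fraction) is fixed by the equation.
#'
#' @param sources Data frame of mixing end-members (see Details).
#' @param aux_params Optional data frame of auxiliary parameters.
#' @param aux_vars Optional auxiliary-variable declaration.
#' @param equation A builtin name (see [builtin_equation_names()]), an
#'   equation object from [parse_model_equation()], or an expression string
#'   (parsed with the declared parameter and variable names).
#' @param equil_value Equilibrated composition used by the `nitrite` builtin
#'   (permil).
#' @param multiplier Per-signature multiplier for the `equilibrium` builtin
#'   when no `mult` parameter is declared.
#' @param margin_mode How range-source analytical margins enter the
#'   likelihood: `"spread"` (widen the range) or `"sigma"` (quadrature).
#' @return An object of class `iso_model`.
#' @examples
#' sources <- tibble::tibble(
#'   name = c("S1", "S2"), mode = "point",
#'   d15N_mean = c(2, 20), d15N_sd = c(2, 4)
#' )
#' m <- iso_model(sources)
#' @export
iso_model <- function(sources, aux_params = NULL, aux_vars = NULL,
                      equation = "mixing", equil_value = 8.6, multiplier = 1,
                      margin_mode = c("spread", "sigma")) {
  margin_mode <- match.arg(margin_mode)
  sources <- tibble::as_tibble(sources)
  if (nrow(sources) == 0) stop_spec("no sources defined")
  if (!all(c("name", "mode") %in% names(sources))) {
    stop_spec("`sources` must have 'name' and 'mode' columns")
  }
  if (anyDuplicated(sources$name)) {
    stop_spec("duplicate source names: %s",
              paste(unique(sources$name[duplicated(sources$name)]),
                    collapse = ", "))
  }
  if (!all(sources$mode %in% c("point", "range"))) {
    stop_spec("source mode must be 'point' or 'range' (row %d)",
              which(!sources$mode %in% c("point", "range"))[1])
  }

  sigs <- infer_signatures(sources)
  if (length(sigs) < 1 || length(sigs) > 3) {
    stop_spec("between 1 and 3 isotope signatures are supported (found %d)",
              length(sigs))
  }
  m <- nrow(sources)
  n <- length(sigs)

  S <- sigma_S <- delta_S <- margin_S <- matrix(
    0, m, n, dimnames = list(sources$name, sigs))
  for (i in seq_len(n)) {
    S[, i] <- sig_col(sources, sigs[i], "_mean")
    sdv <- sig_col(sources, sigs[i], "_sd")
    hrv <- sig_col(sources, sigs[i], "_halfrange")
    mgv <- sig_col(sources, sigs[i], "_margin")
    for (j in seq_len(m)) {
      if (!is.finite(S[j, i])) {
        stop_spec("source '%s': missing %s_mean", sources$name[j], sigs[i])
      }
      if (sources$mode[j] == "point") {
        if (is.finite(hrv[j]) && hrv[j] != 0) {
          stop_spec("source '%s' (point mode) must not set %s_halfrange",
                    sources$name[j], sigs[i])
        }
        if (!is.finite(sdv[j])) {
          stop_spec("source '%s': missing %s_sd", sources$name[j], sigs[i])
        }
        sigma_S[j, i] <- sdv[j]
      } else {
        if (is.finite(sdv[j]) && sdv[j] != 0) {
          stop_spec("source '%s' (range mode) must not set %s_sd",
                    sources$name[j], sigs[i])
        }
        if (!is.finite(hrv[j])) {
          stop_spec("source '%s': missing %s_halfrange", sources$name[j],
                    sigs[i])
        }
        delta_S[j, i] <- hrv[j]
        if (is.finite(mgv[j])) margin_S[j, i] <- mgv[j]
      }
    }
  }
  if (any(sigma_S < 0) || any(delta_S < 0) || any(margin_S < 0)) {
    stop_spec("source uncertainties and half-ranges must be >= 0")
  }

  # auxiliary parameters
  params <- list()
  if (!is.null(aux_params) && nrow(aux_params) > 0) {
    aux_params <- tibble::as_tibble(aux_params)
    if (!"name" %in% names(aux_params)) {
      stop_spec("`aux_params` must have a 'name' column")
    }
    psigs <- infer_signatures(aux_params)
    if (!setequal(psigs, sigs)) {
      stop_spec("aux parameter signatures (%s) do not match sources (%s)",
                paste(psigs, collapse = ","), paste(sigs, collapse = ","))
    }
    for (j in seq_len(nrow(aux_params))) {
      mn <- vapply(sigs, function(s) sig_col(aux_params, s, "_mean")[j], 0)
      sd_ <- vapply(sigs, function(s) sig_col(aux_params, s, "_sd")[j], 0)
      sd_[!is.finite(sd_)] <- 0
      if (any(!is.finite(mn))) {
        stop_spec("aux parameter '%s': missing mean value", aux_params$name[j])
      }
      if (any(sd_ < 0)) {
        stop_spec("aux parameter '%s': sd must be >= 0", aux_params$name[j])
      }
      params[[aux_params$name[j]]] <- list(
        mean = stats::setNames(mn, sigs), sd = stats::setNames(sd_, sigs),
        role = if ("role" %in% names(aux_params)) aux_params$role[j] else NA)
    }
  }

  # auxiliary variables
  if (is.null(aux_vars)) {
    vars <- tibble::tibble(name = character(), lo = numeric(), hi = numeric())
  } else if (is.character(aux_vars)) {
    vars <- tibble::tibble(name = aux_vars, lo = 0, hi = 1)
  } else {
    vars <- tibble::as_tibble(aux_vars)
    if (!"name" %in% names(vars)) stop_spec("`aux_vars` needs a 'name' column")
    if (!"lo" %in% names(vars)) vars$lo <- 0
    if (!"hi" %in% names(vars)) vars$hi <- 1
  }
  if (any(!is.finite(vars$lo)) || any(!is.finite(vars$hi)) ||
      any(vars$lo >= vars$hi)) {
    stop_spec("auxiliary-variable bounds must be finite with lo < hi")
  }

  # equation
  if (is.character(equation)) {
    if (equation %in% builtin_equation_names()) {
      eq <- get_builtin_equation(equation)
    } else {
      eq <- parse_model_equation(equation, m = m, params = names(params),
                                 vars = vars$name)
    }
  } else if (inherits(equation, "isomix_equation")) {
    eq <- equation
  } else {
    stop_spec("`equation` must be a builtin name, expression string or equation object")
  }

  if (m < eq$min_sources || m > eq$max_sources) {
    stop_spec("equation '%s' supports between %d and %s source(s), got %d",
              eq$name, eq$min_sources, format(eq$max_sources), m)
  }
  if (eq$n_vars > nrow(vars)) {
    if (nrow(vars) == 0 && eq$n_vars == 1) {
      vars <- tibble::tibble(name = "r", lo = 0, hi = 1)
    } else {
      stop_spec("equation '%s' needs %d auxiliary variable(s), %d declared",
                eq$name, eq$n_vars, nrow(vars))
    }
  }
  required <- setdiff(eq$param_slots, "mult")
  missing_slots <- setdiff(required, names(params))
  if (length(missing_slots) > 0) {
    stop_spec("equation '%s' requires auxiliary parameter(s) named %s",
              eq$name, paste(missing_slots, collapse = ", "))
  }

  multiplier <- recycle_sig(multiplier, n, "multiplier")
  ctx <- list(
    equil_value = equil_value,
    multiplier = multiplier,
    multiplier_matrix = function(P, N) {
      if (!is.null(P[["mult"]])) P[["mult"]]
      else matrix(multiplier, N, n, byrow = TRUE)
    }
  )

  structure(
    list(signatures = sigs, source_names = sources$name,
         modes = sources$mode, S = S, sigma_S = sigma_S, delta_S = delta_S,
         margin_S = margin_S, margin_mode = margin_mode,
         params = params, vars = vars, equation = eq, ctx = ctx,
         sources = sources,
         aux_params = if (is.null(aux_params)) NULL
                      else tibble::as_tibble(aux_params)),
    class = "iso_model"
  )
}

#' @export
print.iso_model <- function(x, ...) {
  cat(sprintf("<iso_model: %d source(s) x %d signature(s) [%s]; equation: %s>\n",
              nrow(x$S), length(x$signatures),
              paste(x$signatures, collapse = ", "), x$equation$name))
  modes <- paste(sprintf("%s (%s)", x$source_names, x$modes), collapse = ", ")
  cat("  sources:", modes, "\n")
  if (length(x$params)) {
    cat("  aux params:", paste(names(x$params), collapse = ", "), "\n")
  }
  if (nrow(x$vars)) {
    cat("  aux vars:",
        paste(sprintf("%s in [%g, %g]", x$vars$name, x$vars$lo, x$vars$hi),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Construct a measurement
#'
#' @param x Measured delta values, one per signature (permil); may be a named
#'   vector using the model's signature labels.
#' @param sigma_x Per-signature analytical sd (permil, > 0 in at least one
#'   component once combined with source uncertainties).
#' @param id Sample identifier.
#' @return An object of class `iso_measurement`.
#' @export
iso_measurement <- function(x, sigma_x, id = "sample") {
  check_finite(x, "x")
  if (any(sigma_x < 0) || anyNA(sigma_x)) {
    stop_spec("`sigma_x` must be >= 0")
  }
  if (length(sigma_x) == 1L) sigma_x <- rep(sigma_x, length(x))
  if (length(sigma_x) != length(x)) {
    stop_spec("`x` and `sigma_x` lengths differ")
  }
  structure(list(x = as.numeric(x), sigma_x = as.numeric(sigma_x),
                 id = as.character(id), labels = names(x)),
            class = "iso_measurement")
}

#' @export
print.iso_measurement <- function(x, ...) {
  cat(sprintf("<iso_measurement '%s': %s>\n", x$id,
              paste(sprintf("%g +- %g", x$x, x$sigma_x), collapse = ", ")))
  invisible(x)
}

# Coerce one row of a samples tibble (id, <sig>, <sig>_sd) to a measurement
measurement_from_row <- function(row, signatures) {
  x <- vapply(signatures, function(s) as.numeric(row[[s]]), 0)
  sx <- vapply(signatures, function(s) {
    col <- paste0(s, "_sd")
    if (!col %in% names(row)) {
      stop_spec("samples table is missing column '%s'", col)
    }
    as.numeric(row[[col]])
  }, 0)
  iso_measurement(stats::setNames(x, signatures), sx,
                  id = row[["id"]] %||% "sample")
}

as_measurement <- function(sample, model) {
  if (inherits(sample, "iso_measurement")) {
    if (length(sample$x) != length(model$signatures)) {
      stop_spec("measurement has %d signature(s), model has %d",
                length(sample$x), length(model$signatures))
    }
    if (!is.null(sample$labels) &&
        !identical(unname(sample$labels), unname(model$signatures))) {
      stop_spec("measurement signature labels (%s) do not match the model (%s)",
                paste(sample$labels, collapse = ","),
                paste(model$signatures, collapse = ","))
    }
    return(sample)
  }
  if (is.data.frame(sample)) {
    if (nrow(sample) != 1) {
      stop_spec("pass a single sample row to run_chain(); use run_batch() for several")
    }
    missing_cols <- setdiff(model$signatures, names(sample))
    if (length(missing_cols) > 0) {
      stop_spec("samples table is missing signature column(s): %s",
                paste(missing_cols, collapse = ", "))
    }
    return(measurement_from_row(as.list(sample), model$signatures))
  }
  stop_spec("`sample` must be an iso_measurement or a one-row data frame")
}

# Draw auxiliary-parameter matrices (slot name -> N x n), redrawing Gaussian
# parameters at every proposal so their uncertainty is marginalised over.
draw_params <- function(model, N) {
  n <- length(model$signatures)
  out <- list()
  for (nm in names(model$params)) {
    p <- model$params[[nm]]
    if (all(p$sd == 0)) {
      out[[nm]] <- matrix(p$mean, N, n, byrow = TRUE)
    } else {
      out[[nm]] <- matrix(stats::rnorm(N * n, mean = rep(p$mean, each = N),
                                       sd = rep(p$sd, each = N)), N, n)
    }
  }
  out
}

# Fixed parameter matrices at their means (deterministic forward evaluation).
mean_params <- function(model, N) {
  n <- length(model$signatures)
  lapply(model$params, function(p) matrix(p$mean, N, n, byrow = TRUE))
}

# Evaluate the model equation for a block of proposals.
eval_model <- function(model, f, r, P) {
  mu <- model$equation$mu_fun(f, r, P, model$S, model$ctx)
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu), arr.ind = TRUE)[1, ]
    stop_spec("model equation produced a non-finite prediction (signature %s)",
              model$signatures[bad[2]])
  }
  mu
}

#' Forward-evaluate a model at given fractions and process variables
#'
#' Computes the predicted composition, the effective Gaussian sd and the
#' range-induced spread for a single mixing state, with auxiliary parameters
#' held at their means.
#'
#' @param model An [iso_model()].
#' @param f Fraction vector on the simplex.
#' @param r Auxiliary-variable values (may be omitted when the equation has
#'   none).
#' @param sigma_x Optional per-signature measurement sd added in quadrature.
#' @return A tibble with one row per signature: `signature`, `mu`, `sigma`,
#'   `spread`.
#' @export
predict_mu <- function(model, f, r = numeric(), sigma_x = 0) {
  stopifnot(inherits(model, "iso_model"))
  check_simplex(f)
  n <- length(model$signatures)
  fm <- matrix(f, 1)
  rm_ <- matrix(r, 1)
  P <- mean_params(model, 1L)
  mu <- eval_model(model, fm, rm_, P)
  cf <- model$equation$coef_fun(fm, rm_, P, model$S, model$ctx)
  sigma_x <- recycle_sig(sigma_x, n, "sigma_x")
  sig <- spr <- numeric(n)
  for (i in seq_len(n)) {
    sig[i] <- sqrt(sigma_x[i]^2 + sum(cf[[i]][1, ]^2 * sigma_eff(model)[, i]^2))
    spr[i] <- sum(abs(cf[[i]][1, ]) * delta_eff(model)[, i])
  }
  tibble::tibble(signature = model$signatures,
                 mu = unname(drop(mu))[seq_len(n)],
                 sigma = sig, spread = spr)
}

# Effective per-source sd / half-range after routing analytical margins.
sigma_eff <- function(model) {
  if (model$margin_mode == "sigma") {
    sqrt(model$sigma_S^2 + model$margin_S^2)
  } else {
    model$sigma_S
  }
}

delta_eff <- function(model) {
  if (model$margin_mode == "spread") {
    model$delta_S + model$margin_S
  } else {
    model$delta_S
  }
}
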