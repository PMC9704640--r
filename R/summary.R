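# Posterior summaries, correlations and model-adequacy diagnostics.

ci_probs <- function(level) {
  half <- level / 2
  c(0.5 - half, 0.5 + half)
}

#' Summarise a chain's posterior distributions
#'
#' Per sampled variable (mixing fractions and process variables): mean,
#' median, sd, and the central credible intervals that enclose 68.28% and
#' 95.45% of the distribution around the median (the direct analogues of the
#' 1-sigma and 2-sigma intervals, guaranteed to stay inside the variables'
#' `[0, 1]` domain). Quantiles use linear interpolation between order
#' statistics.
#'
#' @param chain An [run_chain()] result.
#' @return A tibble with columns `variable`, `mean`, `median`, `sd`,
#'   `ci68_lo`, `ci68_hi`, `ci95_lo`, `ci95_hi`, `n`.
#' @export
posterior_summary <- function(chain) {
  ent <- chain_entries(chain)
  if (nrow(ent) == 0) stop_spec("empty chain after burn-in removal")
  vars <- chain_variables(chain)
  p68 <- ci_probs(0.6828)
  p95 <- ci_probs(0.9545)
  purrr::map_dfr(vars, function(v) {
    xs <- ent[[v]]
    q <- stats::quantile(xs, c(p68, p95), names = FALSE, type = 7)
    tibble::tibble(variable = v, mean = mean(xs), median = stats::median(xs),
                   sd = stats::sd(xs), ci68_lo = q[1], ci68_hi = q[2],
                   ci95_lo = q[3], ci95_hi = q[4], n = length(xs))
  })
}

#' @rdname posterior_summary
#' @param x An `iso_chain` object.
#' @param ... Unused.
#' @method tidy iso_chain
#' @export
tidy.iso_chain <- function(x, ...) posterior_summary(x)

#' One-row overview of a sampler run
#'
#' @param x An `iso_chain` object.
#' @param ... Unused.
#' @return A one-row tibble: entries, burn-in, iterations used, acceptance
#'   rate, exhaustion flag, method and equation name.
#' @method glance iso_chain
#' @export
glance.iso_chain <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(chain_entries(x)), burn_in = x$burn_in,
    iterations = x$iterations, accepted = x$accepted,
    acceptance_rate = x$acceptance_rate, exhausted = x$exhausted,
    method = x$method, equation = x$model$equation$name,
    sample_id = x$measurement$id)
}

#' Pairwise Pearson correlations of the sampled variables
#'
#' @param chain An `iso_chain` object.
#' @return A symmetric correlation matrix with unit diagonal over the sampled
#'   variables. A zero-variance variable yields `NA` entries (undefined
#'   correlation) rather than 0, so degenerate models stay visible.
#' @export
correlation_matrix <- function(chain) {
  ent <- chain_entries(chain)
  vars <- chain_variables(chain)
  if (nrow(ent) < 2 || length(vars) < 2) {
    stop_spec("correlations need at least 2 entries and 2 variables")
  }
  xs <- as.matrix(ent[vars])
  sds <- apply(xs, 2, stats::sd)
  out <- suppressWarnings(stats::cor(xs))
  out[sds == 0, ] <- NA_real_
  out[, sds == 0] <- NA_real_
  diag(out) <- ifelse(sds == 0, NA_real_, 1)
  out
}

#' Model-adequacy z-scores
#'
#' Standardised distance between each measured signature and the chain-mean
#' prediction: `z = |x - mu_bar| / (sigma / sqrt(n))`, where `mu_bar` and
#' `sigma` are the mean and sd of the chain of predicted compositions and `n`
#' the number of entries. When range-mode sources give the prediction a
#' finite spread, `z` is set to 0 whenever `mu_bar` lies within `x +- Delta`,
#' and otherwise uses the distance to the nearer band edge,
#' `min(|x - mu_bar - Delta|, |x - mu_bar + Delta|)`. Because the
#' denominator is a standard error, `z` grows with chain length for a fixed
#' discrepancy; the scale-free ratio `|x - mu_bar| / sigma` is reported
#' alongside as supplementary context.
#'
#' @param chain An `iso_chain` object.
#' @param spread Per-signature band half-width `Delta`; defaults to the mean
#'   spread over chain entries.
#' @return A tibble with one row per signature: `signature`, `x`, `mu_bar`,
#'   `sigma_mu`, `spread`, `z`, `rejection_probability`, `ratio`.
#' @export
z_scores <- function(chain, spread = NULL) {
  ent <- chain_entries(chain)
  if (nrow(ent) < 2) stop_spec("z-scores need at least 2 chain entries")
  sigs <- chain$model$signatures
  x <- chain$measurement$x
  n <- nrow(ent)
  out <- purrr::map_dfr(seq_along(sigs), function(i) {
    mu <- ent[[paste0("mu_", sigs[i])]]
    del <- if (is.null(spread)) mean(ent[[paste0("spread_", sigs[i])]])
           else recycle_sig(spread, length(sigs), "spread")[i]
    mu_bar <- mean(mu)
    s <- stats::sd(mu)
    dev <- abs(x[i] - mu_bar)
    z <- if (dev <= del) 0
         else min(abs(x[i] - mu_bar - del), abs(x[i] - mu_bar + del)) /
           (s / sqrt(n))
    tibble::tibble(signature = sigs[i], x = x[i], mu_bar = mu_bar,
                   sigma_mu = s, spread = del, z = z,
                   rejection_probability = z_to_probability(z),
                   ratio = if (s > 0) dev / s else NA_real_)
  })
  out
}

#' Convert a z-score to a rejection probability
#'
#' Two-sided normal tail mass: the probability of rejecting the hypothesis
#' that the data were generated under the model, `erf(z / sqrt(2))`. A
#' z-score of 2 maps to about 95.45%, 3 to about 99.73%.
#'
#' @param z Non-negative z-score(s).
#' @return Probability in `[0, 1]`, same length as `z`.
#' @export
z_to_probability <- function(z) {
  if (any(z < 0)) stop_spec("`z` must be >= 0")
  erf(z / sqrt(2))
}

#' Two-chain convergence check
#'
#' Compares two independent runs variable by variable with a two-sample
#' z-statistic `|m_a - m_b| / sqrt(s_a^2/n_a + s_b^2/n_b)`; the check fails
#' when any variable exceeds `z_max`. Identical chains give z = 0 throughout.
#'
#' @param chain_a,chain_b Two `iso_chain` objects over the same variables.
#' @param z_max Failure threshold (default 3).
#' @return A tibble (`variable`, `mean_a`, `mean_b`, `z`) with attribute
#'   `converged`; also accessible via `attr(, "converged")`.
#' @export
two_chain_convergence <- function(chain_a, chain_b, z_max = 3) {
  va <- chain_variables(chain_a)
  vb <- chain_variables(chain_b)
  if (!identical(va, vb)) {
    stop_spec("chains sample different variables (%s vs %s)",
              paste(va, collapse = ","), paste(vb, collapse = ","))
  }
  ea <- chain_entries(chain_a)
  eb <- chain_entries(chain_b)
  out <- purrr::map_dfr(va, function(v) {
    xa <- ea[[v]]
    xb <- eb[[v]]
    se <- sqrt(stats::sd(xa)^2 / length(xa) + stats::sd(xb)^2 / length(xb))
    z <- if (se == 0) 0 else abs(mean(xa) - mean(xb)) / se
    tibble::tibble(variable = v, mean_a = mean(xa), mean_b = mean(xb), z = z)
  })
  attr(out, "converged") <- all(out$z <= z_max)
  out
}
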