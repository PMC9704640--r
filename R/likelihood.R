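# Likelihood of a measurement given a model prediction.
#
# Point-mode sources contribute Gaussian sd (combined in quadrature with the
# analytical sd of the sample); range-mode sources contribute a uniform band
# of half-width Delta ("spread") around the prediction, handled through the
# convolution of a Gaussian with a uniform density, i.e. a difference of erf
# terms. Sampling uses the un-normalised forms (the printed model equations);
# `normalized = TRUE` exposes the proper density for diagnostics.

#' Gaussian measurement likelihood
#'
#' Product over signatures of normal densities
#' `prod_i N(x_i | mu_i, sigma_i)`; the form used when all sources are
#' defined as points with uncertainties.
#'
#' @param x Measured values per signature.
#' @param mu Predicted values per signature.
#' @param sigma Effective sd per signature (> 0), typically from
#'   [combine_sigma()].
#' @return A single non-negative likelihood value.
#' @export
gaussian_likelihood <- function(x, mu, sigma) {
  if (any(sigma <= 0)) {
    stop_spec("`sigma` must be > 0", class = "isomix_domain_error")
  }
  prod(stats::dnorm(x, mu, sigma))
}

#' Range (erf-convolved uniform) measurement likelihood
#'
#' Per signature, the likelihood of `x` when the prediction is a uniform band
#' `mu +- spread` observed with Gaussian noise `sigma`:
#' `erf((x - mu + spread) / (sigma * sqrt(2))) -
#'  erf((x - mu - spread) / (sigma * sqrt(2)))`,
#' taken as upper minus lower so the value is non-negative; the product is
#' returned over signatures. The un-normalised form (default) is what the
#' sampler maximises; with `normalized = TRUE` each factor is divided by
#' `4 * spread`, giving the Gaussian-uniform convolution density, which
#' integrates to one over `x` and converges to [gaussian_likelihood()] as
#' `spread` tends to 0 (the `spread = 0` limit is returned as the Gaussian
#' density in normalized mode and as exactly 0 otherwise).
#'
#' @inheritParams gaussian_likelihood
#' @param spread Half-width of the predicted band per signature (>= 0),
#'   typically from [compute_spread()].
#' @param normalized Return the proper convolution density instead of the
#'   un-normalised erf difference.
#' @return A single non-negative value.
#' @export
range_likelihood <- function(x, mu, sigma, spread, normalized = FALSE) {
  if (any(sigma <= 0)) {
    stop_spec("`sigma` must be > 0", class = "isomix_domain_error")
  }
  if (any(spread < 0)) {
    stop_spec("`spread` must be >= 0", class = "isomix_domain_error")
  }
  upper <- (x - mu + spread) / (sigma * sqrt(2))
  lower <- (x - mu - spread) / (sigma * sqrt(2))
  val <- erf(upper) - erf(lower)
  if (normalized) {
    val <- ifelse(spread > 0, val / (4 * spread), stats::dnorm(x, mu, sigma))
  }
  prod(pmax(val, 0))
}

#' Combine measurement and point-source uncertainties
#'
#' Effective Gaussian sd per signature:
#' `sigma_i = sqrt(sigma_x_i^2 + sum_j (c_{j,i} sigma_{S_j,i})^2)`, where the
#' sensitivity `c_{j,i} = d mu_i / d S_{j,i}` equals `f_j` for plain mixing
#' (the default when `coef` is not given). Range-mode sources carry no sd
#' here — their half-ranges enter through [compute_spread()]. Optional
#' analytically-propagated parameter terms can be supplied through
#' `aux_partials`/`aux_sigmas` (each a per-signature vector, added in
#' quadrature); by default parameter uncertainty is instead marginalised by
#' redrawing during sampling.
#'
#' @param sigma_x Per-signature measurement sd.
#' @param f Fraction vector (length m).
#' @param source_sigmas `m x n` matrix (or length-m vector for one signature)
#'   of point-source sds; use 0 rows for range-mode sources.
#' @param coef Optional `m x n` sensitivity matrix replacing the default
#'   `f_j` weights.
#' @param aux_partials,aux_sigmas Optional per-signature sensitivity and sd
#'   vectors for analytically-propagated auxiliary parameters.
#' @return Per-signature sd vector.
#' @examples
#' combine_sigma(0.1, c(0.5, 0.5), c(2, 4))  # sqrt(0.01 + 1 + 4)
#' @export
combine_sigma <- function(sigma_x, f, source_sigmas, coef = NULL,
                          aux_partials = NULL, aux_sigmas = NULL) {
  source_sigmas <- as.matrix(source_sigmas)
  m <- nrow(source_sigmas)
  n <- ncol(source_sigmas)
  if (length(f) != m) stop_spec("length(f) does not match source_sigmas rows")
  sigma_x <- recycle_sig(sigma_x, n, "sigma_x")
  if (is.null(coef)) coef <- matrix(f, m, n)
  tot <- sigma_x^2 + colSums((as.matrix(coef) * source_sigmas)^2)
  if (!is.null(aux_partials)) {
    tot <- tot + recycle_sig(aux_partials, n, "aux_partials")^2 *
      recycle_sig(aux_sigmas, n, "aux_sigmas")^2
  }
  out <- sqrt(tot)
  if (all(out == 0)) {
    stop_spec("degenerate likelihood: total sd is zero for every signature",
              class = "isomix_domain_error")
  }
  out
}

#' Spread of the prediction induced by range-mode sources
#'
#' Half-width of the predicted band per signature:
#' `Delta_i = sum_j |c_{j,i}| * DeltaS_{j,i}`, with sensitivities
#' `c_{j,i} = f_j` for plain mixing (default). Point-mode sources contribute
#' rows of zeros.
#'
#' @param f Fraction vector (length m).
#' @param half_ranges `m x n` matrix (or length-m vector) of source
#'   half-ranges (>= 0).
#' @param coef Optional `m x n` sensitivity matrix.
#' @param aux_terms Optional per-signature additive spread from auxiliary
#'   parameters expressed as ranges.
#' @return Per-signature spread vector (>= 0).
#' @examples
#' compute_spread(c(0.5, 0.5), c(2, 4))  # 3
#' @export
compute_spread <- function(f, half_ranges, coef = NULL, aux_terms = NULL) {
  half_ranges <- as.matrix(half_ranges)
  if (any(half_ranges < 0)) stop_spec("`half_ranges` must be >= 0")
  m <- nrow(half_ranges)
  n <- ncol(half_ranges)
  if (length(f) != m) stop_spec("length(f) does not match half_ranges rows")
  if (is.null(coef)) coef <- matrix(f, m, n)
  out <- colSums(abs(as.matrix(coef)) * half_ranges)
  if (!is.null(aux_terms)) out <- out + recycle_sig(aux_terms, n, "aux_terms")
  out
}

# Bulk likelihood for a block of proposals.
# Returns list(L, mu, sigma, spread) with N rows. Per signature the erf form
# is used when range sources can reach it (any positive effective half-range),
# the Gaussian form otherwise; `mode` can force one of the two.
block_likelihood <- function(model, meas, f, r, P,
                             mode = c("auto", "point", "range")) {
  mode <- match.arg(mode)
  n <- length(model$signatures)
  N <- nrow(f)
  mu <- eval_model(model, f, r, P)
  cf <- model$equation$coef_fun(f, r, P, model$S, model$ctx)
  sS <- sigma_eff(model)
  dS <- delta_eff(model)
  sigma <- spread <- matrix(0, N, n)
  L <- rep(1, N)
  for (i in seq_len(n)) {
    ci <- cf[[i]]
    sigma[, i] <- sqrt(meas$sigma_x[i]^2 +
                         as.vector((ci^2) %*% (sS[, i]^2)))
    spread[, i] <- as.vector(abs(ci) %*% dS[, i])
    if (any(sigma[, i] <= 0)) {
      stop_spec(paste0("degenerate likelihood for signature '%s': ",
                       "zero total sd (give the sample or a point source a ",
                       "positive sd)"), model$signatures[i],
                class = "isomix_domain_error")
    }
    use_range <- switch(mode,
                        auto = any(dS[, i] > 0),
                        point = FALSE,
                        range = any(dS[, i] > 0))
    if (use_range) {
      up <- (meas$x[i] - mu[, i] + spread[, i]) / (sigma[, i] * sqrt(2))
      lo <- (meas$x[i] - mu[, i] - spread[, i]) / (sigma[, i] * sqrt(2))
      L <- L * pmax(erf(up) - erf(lo), 0)
    } else {
      L <- L * stats::dnorm(meas$x[i], mu[, i], sigma[, i])
    }
  }
  list(L = L, mu = mu, sigma = sigma, spread = spread)
}
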