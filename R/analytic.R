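# Closed-form solvers for the exactly determined mixing cases. These are both
# product features and the independent cross-checks for the sampler.

#' Exact two-source mixing fractions (one signature)
#'
#' Solves `x = f1 S1 + f2 S2`, `f1 + f2 = 1`:
#' `f1 = (S2 - x) / (S2 - S1)`, `f2 = (x - S1) / (S2 - S1)`.
#'
#' @param x Measured mixture value (permil).
#' @param S1,S2 Source values (permil), `S1 != S2`.
#' @return Named vector `c(f1, f2)` summing to 1.
#' @examples
#' solve_two_source(11, 2, 20)  # c(0.5, 0.5)
#' @export
solve_two_source <- function(x, S1, S2) {
  check_finite(c(x, S1, S2), "inputs")
  if (S1 == S2) {
    stop_spec("singular system: S1 == S2", class = "isomix_domain_error")
  }
  f1 <- (S2 - x) / (S2 - S1)
  c(f1 = f1, f2 = 1 - f1)
}

#' First-order uncertainty of the two-source solution
#'
#' Delta-method propagation of the measurement and source uncertainties
#' through the exact solution:
#' `sigma_f1^2 = (df1/dx)^2 sigma_x^2 + (df1/dS1)^2 dS1^2 +
#'  (df1/dS2)^2 dS2^2` with `df1/dx = -1/(S2-S1)`,
#' `df1/dS1 = (S2-x)/(S2-S1)^2`, `df1/dS2 = (x-S1)/(S2-S1)^2`. Because
#' `f1 + f2 = 1`, the two fractions share the same sd.
#'
#' @inheritParams solve_two_source
#' @param sigma_x Measurement sd.
#' @param dS1,dS2 Source uncertainties (sd or half-range, in the same role as
#'   used for the solution).
#' @return Named vector `c(sigma_f1, sigma_f2)` (equal values).
#' @examples
#' propagate_two_source_sd(11, 2, 20, 0.1, 2, 4)  # ~0.124
#' @export
propagate_two_source_sd <- function(x, S1, S2, sigma_x, dS1, dS2) {
  check_finite(c(x, S1, S2), "inputs")
  if (S1 == S2) {
    stop_spec("singular system: S1 == S2", class = "isomix_domain_error")
  }
  if (any(c(sigma_x, dS1, dS2) < 0)) stop_spec("uncertainties must be >= 0")
  d <- S2 - S1
  s2 <- (1 / d)^2 * sigma_x^2 + ((S2 - x) / d^2)^2 * dS1^2 +
    ((x - S1) / d^2)^2 * dS2^2
  s <- sqrt(s2)
  c(sigma_f1 = s, sigma_f2 = s)
}

#' Feasible fraction intervals for range-defined sources (one signature)
#'
#' When each source may take any value within `S_i +- dS_i` with equal
#' probability, the exact solution becomes an interval per fraction: the
#' extremes of `f1 = (S2 - x)/(S2 - S1)` over the rectangle of admissible
#' `(S1, S2)` pairs. For a measurement between the ranges the extremes occur
#' at the paired range endpoints
#' `f1 in ((S2-dS2-x)/(S2-dS2-S1+dS1), (S2+dS2-x)/(S2+dS2-S1-dS1))`
#' (and the complementary interval for `f2`); the bounds are clipped to
#' `[0, 1]`. If even the extreme source values cannot produce `x`, the
#' solution is flagged infeasible.
#'
#' @inheritParams solve_two_source
#' @param dS1,dS2 Source half-ranges (>= 0).
#' @return List with elements `f1` and `f2` (each `c(lo, hi)`) and
#'   `feasible`.
#' @export
two_source_range_bounds <- function(x, S1, dS1, S2, dS2) {
  check_finite(c(x, S1, dS1, S2, dS2), "inputs")
  if (any(c(dS1, dS2) < 0)) stop_spec("half-ranges must be >= 0")
  corners_S1 <- c(S1 - dS1, S1 + dS1)
  corners_S2 <- c(S2 - dS2, S2 + dS2)
  grid <- expand.grid(s1 = corners_S1, s2 = corners_S2)
  if (any(grid$s1 == grid$s2)) {
    stop_spec("singular system: source ranges touch",
              class = "isomix_domain_error")
  }
  f1s <- (grid$s2 - x) / (grid$s2 - grid$s1)
  lo <- min(f1s)
  hi <- max(f1s)
  feasible <- hi >= 0 && lo <= 1
  clip <- function(v) pmin(pmax(v, 0), 1)
  list(f1 = c(lo = clip(lo), hi = clip(hi)),
       f2 = c(lo = clip(1 - hi), hi = clip(1 - lo)),
       feasible = feasible)
}

#' Exact mixing fractions for the square system (m = n + 1 sources)
#'
#' Solves the augmented linear system `[S^T; 1] f = [x; 1]` that determines
#' `n + 1` source fractions from `n` signatures. Fractions always sum to 1;
#' if any falls outside `[0, 1]` the measurement lies outside the mixing
#' polygon and the solution is flagged infeasible rather than rejected.
#'
#' @param x Measured vector (length n).
#' @param S Source matrix, `m x n` with `m = n + 1` (sources in rows).
#' @return List with `fractions` (named when S has row names) and `feasible`.
#' @examples
#' solve_sources(c(10, 10), rbind(c(0, 0), c(10, 30), c(20, 0)))
#' @export
solve_sources <- function(x, S) {
  S <- as.matrix(S)
  n <- length(x)
  m <- nrow(S)
  if (ncol(S) != n) stop_spec("S must have one column per signature")
  if (m > n + 1) {
    stop_spec(paste0("no unique solution: %d sources exceed %d signature(s) ",
                     "+ 1; use the sampler for under-determined systems"),
              m, n)
  }
  if (m < n + 1) {
    stop_spec("need m = n + 1 sources for a square system (got m = %d, n = %d)",
              m, n)
  }
  A <- rbind(t(S), rep(1, m))
  b <- c(x, 1)
  f <- tryCatch(solve(A, b), error = function(e) {
    stop_spec("singular mixing system (collinear sources)",
              class = "isomix_domain_error")
  })
  feasible <- all(f >= -1e-12) && all(f <= 1 + 1e-12)
  names(f) <- rownames(S)
  list(fractions = f, feasible = feasible)
}

#' Closed-form evaporation-to-inflow ratio
#'
#' Inverts the Craig-Gordon enrichment `mu = (r A D + mu0)/(r A + 1)` for the
#' evaporated fraction: `r = (mu - mu0) / (A (D - mu))`. Round-trips with
#' [craig_gordon_mu()] to machine precision.
#'
#' @param mu Lake-water (evaporated) composition (permil).
#' @param mu0 Inflow composition (permil).
#' @param A Humidity/temperature-dependent slope parameter.
#' @param D Limiting isotopic enrichment (permil).
#' @return Evaporation-to-inflow ratio `r`.
#' @examples
#' invert_evaporation(-2, -5, 1.7881, 5.6063)  # 0.2206
#' @export
invert_evaporation <- function(mu, mu0, A, D) {
  check_finite(c(mu, mu0, A, D), "inputs")
  denom <- A * (D - mu)
  if (any(abs(denom) < 1e-12)) {
    stop_spec("singular inversion: A * (D - mu) = 0",
              class = "isomix_domain_error")
  }
  (mu - mu0) / denom
}
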