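#' Isotopic composition of a pure mixture
#'
#' Mass-balance mixing of `m` end-members: per signature `i`,
#' `mu0_i = sum_j f_j * S[j, i]`. The result is a convex combination of the
#' source signatures and therefore always lies inside the mixing polygon.
#'
#' @param f Fraction vector of length `m`; must sum to 1 with all entries in
#'   `[0, 1]`.
#' @param S Source signatures: an `m x n` matrix (sources in rows, signatures
#'   in columns) or a length-`m` vector for a single signature.
#' @return Numeric vector of length `n` with the mixture delta values (permil).
#' @examples
#' mix_mu0(c(0.2, 0.6, 0.2), c(5, -16.5, 3))   # -8.3
#' @export
mix_mu0 <- function(f, S) {
  S <- as.matrix(S)
  if (length(f) != nrow(S)) {
    stop_spec("length(f) = %d does not match the %d source rows of S",
              length(f), nrow(S))
  }
  check_finite(S, "S")
  check_simplex(f)
  drop(crossprod(f, S))[seq_len(ncol(S))]
}

check_simplex <- function(f, tol = 1e-8) {
  check_prob(f, "f")
  if (abs(sum(f) - 1) > tol) {
    stop_spec("fractions must sum to 1 (got %.10f)", sum(f),
              class = "isomix_domain_error")
  }
  invisible(f)
}

#' Open-system (steady-state) fractionation shift
#'
#' Linear offset of a mixture composition by a fractionation factor under
#' continuous substrate replenishment. Two conventions are in use and are kept
#' explicit: with `convention = "residual"` the offset is `mu0 - A * (1 - r)`
#' where `r` is the residual unreacted fraction (`r = 1` means no reaction);
#' with `convention = "reduced"` it is `mu0 - A * r` where `r` is the reacted
#' (e.g. reduced-nitrate) fraction (`r = 0` means no reaction).
#'
#' @param mu0 Pre-process mixture composition per signature (permil).
#' @param A Fractionation factor(s), one value per signature (permil).
#' @param r Process-progress fraction in `[0, 1]` (see `convention`).
#' @param convention `"residual"` or `"reduced"`, as above.
#' @return Shifted composition, same length as `mu0`.
#' @examples
#' open_system_shift(10, -5, 0.5)                       # 12.5
#' open_system_shift(c(-8.3, 8.1), c(-15.9, -8), 0.6, "reduced")  # c(1.24, 12.9)
#' @export
open_system_shift <- function(mu0, A, r, convention = c("residual", "reduced")) {
  convention <- match.arg(convention)
  check_finite(mu0, "mu0")
  check_prob(r, "r")
  A <- recycle_sig(A, length(mu0), "A")
  if (convention == "residual") mu0 - A * (1 - r) else mu0 - A * r
}

#' Rayleigh (closed-system) fractionation shift
#'
#' Residual-pool enrichment `mu = mu0 + A * ln(r)` with `r` the residual
#' unreacted fraction; `r = 1` leaves the mixture unchanged and the logarithm
#' makes the shift unbounded as `r` approaches 0.
#'
#' @inheritParams open_system_shift
#' @param r Residual fraction in `(0, 1]`.
#' @return Shifted composition, same length as `mu0`.
#' @examples
#' rayleigh_shift(0.9 * -47.6 + 0.1 * -37.8, -7.1, 0.8)  # -45.0
#' @export
rayleigh_shift <- function(mu0, A, r) {
  check_finite(mu0, "mu0")
  if (!is.numeric(r) || anyNA(r) || any(r <= 0) || any(r > 1)) {
    stop_spec("`r` must lie in (0, 1] for closed-system fractionation",
              class = "isomix_domain_error")
  }
  A <- recycle_sig(A, length(mu0), "A")
  mu0 + A * log(r)
}

#' Equilibrium-exchange shift
#'
#' Abiotic convergence toward an equilibrium composition `E`, weighted by the
#' equilibrated fraction `r`, optionally scaled per signature by a multiplier:
#' `mu_i = mu0_i * (1 - r * m_i) + E_i * r * m_i`. With `r * m_i = 1` the
#' composition equals `E_i` exactly.
#'
#' @inheritParams open_system_shift
#' @param E Equilibrium endpoint per signature (permil).
#' @param r Equilibrated fraction in `[0, 1]`.
#' @param multiplier Per-signature non-negative multiplier on `r`
#'   (default 1); `r * multiplier` must not exceed 1.
#' @return Shifted composition, same length as `mu0`.
#' @export
equilibrium_shift <- function(mu0, E, r, multiplier = 1) {
  check_finite(mu0, "mu0")
  check_prob(r, "r")
  E <- recycle_sig(E, length(mu0), "E")
  multiplier <- recycle_sig(multiplier, length(mu0), "multiplier")
  if (any(multiplier < 0)) stop_spec("`multiplier` must be >= 0",
                                     class = "isomix_domain_error")
  w <- r * multiplier
  if (any(w > 1 + 1e-12)) {
    stop_spec("r * multiplier exceeds 1 (got %.4f)", max(w),
              class = "isomix_domain_error")
  }
  mu0 * (1 - w) + E * w
}

#' Craig-Gordon evaporative enrichment
#'
#' Steady-state isotopic enrichment of evaporating surface water,
#' `mu = (r * A * D + mu0) / (r * A + 1)`, where `r` is the
#' evaporation-to-inflow flux ratio (E/I), `A` depends on relative humidity
#' and temperature, and `D` is the limiting enrichment. At `r = 0` the inflow
#' composition `mu0` is returned; for `A > 0` the composition moves
#' monotonically toward `D` as `r` grows.
#'
#' @inheritParams open_system_shift
#' @param A Humidity/temperature-dependent slope parameter per signature.
#' @param D Limiting isotopic enrichment per signature (permil).
#' @param r Evaporated fraction (E/I), `r >= 0`.
#' @return Lake-water composition, same length as `mu0`.
#' @examples
#' craig_gordon_mu(-5, 1.7881, 5.6063, 0.2206)  # ~ -2.0
#' @export
craig_gordon_mu <- function(mu0, A, D, r) {
  check_finite(mu0, "mu0")
  if (!is.numeric(r) || anyNA(r) || any(r < 0)) {
    stop_spec("`r` must be >= 0", class = "isomix_domain_error")
  }
  A <- recycle_sig(A, length(mu0), "A")
  D <- recycle_sig(D, length(mu0), "D")
  denom <- r * A + 1
  if (any(abs(denom) < 1e-12)) {
    stop_spec("singular evaporation model: r * A = -1",
              class = "isomix_domain_error")
  }
  (r * A * D + mu0) / denom
}

#' Nitrite pathway mixing with consumption fractionation and O equilibration
#'
#' Forward model for nitrite formed by nitrate reduction (NAR), ammonium
#' oxidation (AOX) and organic-N oxidation (ORG), consumed by nitrite
#' reduction and nitrite oxidation in a fixed 0.7:0.3 flux ratio (open
#' system), with optional oxygen-isotope equilibration toward an equilibrium
#' value: per signature `i`,
#' `mu_i = (sum_j f_j S[j,i] - 0.7 A_i - 0.3 B_i) * (1 - C_i) + equil * C_i`.
#'
#' @param f Fractions of the three formation pathways (simplex).
#' @param S `3 x n` matrix of pathway signatures.
#' @param A Fractionation factor of nitrite reduction per signature (permil).
#' @param B Fractionation factor of nitrite oxidation per signature (permil).
#' @param C Equilibrated fraction per signature in `[0, 1]` (nonzero only for
#'   oxygen signatures).
#' @param equil_value Composition after complete equilibration with water
#'   (permil); default 8.6.
#' @return Nitrite composition per signature.
#' @export
nitrite_mu <- function(f, S, A, B, C, equil_value = 8.6) {
  mu0 <- mix_mu0(f, S)
  n <- length(mu0)
  A <- recycle_sig(A, n, "A")
  B <- recycle_sig(B, n, "B")
  C <- recycle_sig(C, n, "C")
  check_prob(C, "C")
  (mu0 - 0.7 * A - 0.3 * B) * (1 - C) + equil_value * C
}

#' N2O pathway mixing with Rayleigh reduction
#'
#' Mixture of N2O production pathways (typically bacterial denitrification,
#' nitrifier denitrification, fungal denitrification and nitrification)
#' followed by closed-system fractionation during partial reduction to N2:
#' `mu = sum_j f_j S_j + A * ln(r)` with `r` the residual unreduced fraction.
#'
#' @param f Pathway fractions (simplex).
#' @param S `m x n` matrix of pathway signatures.
#' @param A Reduction fractionation factor per signature (permil).
#' @param r Residual unreduced N2O fraction in `(0, 1]`.
#' @return N2O composition per signature.
#' @export
n2o_mu <- function(f, S, A, r) {
  rayleigh_shift(mix_mu0(f, S), A, r)
}

#' Recalculate a nitrification-derived nitrate end-member
#'
#' Converts an ammonium source measured as `d15N_NH4` into the nitrate
#' end-member it produces on nitrification: nitrogen inherits the ammonium
#' signature shifted by the nitrification fractionation
#' (`d15N_NO3 = d15N_NH4 + eps_nit`), and nitrate oxygen is assembled from
#' ambient water and atmospheric O2 in a 2:1 ratio
#' (`d18O_NO3 = (2/3) d18O_H2O + (1/3) d18O_O2`).
#'
#' @param d15N_NH4 Ammonium nitrogen signature (permil).
#' @param eps_nit Net nitrification N fractionation (permil, typically
#'   negative).
#' @param d18O_H2O Ambient water oxygen signature (permil).
#' @param d18O_O2 Atmospheric O2 signature (permil), 23.5 by convention.
#' @return Named numeric vector `c(d15N_NO3, d18O_NO3)`.
#' @examples
#' recalc_nitrification_source(0.5, -17, 5, 23.5)    # c(-16.5, 11.2)
#' recalc_nitrification_source(20, -17, -5, 23.5)    # c(3.0, 4.5)
#' @export
recalc_nitrification_source <- function(d15N_NH4, eps_nit, d18O_H2O,
                                        d18O_O2 = 23.5) {
  check_finite(c(d15N_NH4, eps_nit, d18O_H2O, d18O_O2), "inputs")
  c(d15N_NO3 = d15N_NH4 + eps_nit,
    d18O_NO3 = (2 / 3) * d18O_H2O + (1 / 3) * d18O_O2)
}
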