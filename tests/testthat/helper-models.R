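# Small model builders shared across tests.

two_source_point_model <- function() {
  iso_model(tibble::tibble(
    name = c("S1", "S2"), mode = "point",
    I1_mean = c(2, 20), I1_sd = c(2, 4)))
}

two_source_range_model <- function() {
  iso_model(tibble::tibble(
    name = c("S1", "S2"), mode = "range",
    I1_mean = c(2, 20), I1_halfrange = c(2, 4)))
}

one_sig_sample <- function(x = 11, sd = 0.1, id = "x1") {
  tibble::tibble(id = id, I1 = x, I1_sd = sd)
}

# dense-grid posterior oracle for 1D two-source problems: evaluates an
# explicitly written likelihood (independent of the package's internals) on a
# fraction grid and returns the normalised weights
grid_posterior_1d <- function(lik_fun, n_grid = 20001) {
  g <- seq(0, 1, length.out = n_grid)
  w <- vapply(g, lik_fun, 0)
  list(grid = g, w = w / sum(w),
       mean = sum(g * w) / sum(w),
       sd = sqrt(sum((g - sum(g * w) / sum(w))^2 * w) / sum(w)),
       cdf = cumsum(w) / sum(w))
}

ks_against_grid <- function(draws, oracle) {
  max(abs(stats::ecdf(draws)(oracle$grid) - oracle$cdf))
}
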