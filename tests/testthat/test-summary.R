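# Build a synthetic iso_chain directly so summary functions can be tested
# against known distributions without running the sampler.
fake_chain <- function(df, signatures = character(), x = numeric(),
                       burn_in = 0L) {
  entries <- tibble::as_tibble(df)
  entries$iteration <- seq_len(nrow(entries))
  entries$likelihood <- 1
  model <- list(signatures = signatures,
                source_names = sub("^f_", "", grep("^f_", names(df),
                                                   value = TRUE)),
                equation = list(name = "mixing"))
  structure(list(entries = entries, burn_in = burn_in,
                 iterations = nrow(entries), accepted = nrow(entries),
                 acceptance_rate = 1, exhausted = FALSE,
                 method = "threshold", model = model,
                 measurement = list(x = x, sigma_x = rep(1, length(x)),
                                    id = "fake")),
            class = "iso_chain")
}

test_that("credible intervals enclose the central mass around the median", {
  set.seed(41)
  u <- runif(1e5)
  ch <- fake_chain(tibble::tibble(f_a = u, f_b = 1 - u))
  ps <- posterior_summary(ch)
  row <- ps[ps$variable == "f_a", ]
  expect_equal(row$ci68_lo, 0.5 - 0.3414, tolerance = 0.01)
  expect_equal(row$ci68_hi, 0.5 + 0.3414, tolerance = 0.01)
  expect_equal(row$mean, 0.5, tolerance = 0.005)
  # the CI truly contains 68.28% of the chain and brackets the median
  frac <- mean(u >= row$ci68_lo & u <= row$ci68_hi)
  expect_gte(frac, 0.680)
  expect_lte(frac, 0.686)
  expect_true(row$ci68_lo <= row$median && row$median <= row$ci68_hi)
  expect_true(row$ci95_lo <= row$median && row$median <= row$ci95_hi)
})

test_that("a constant chain summarises to a degenerate distribution", {
  ch <- fake_chain(tibble::tibble(f_a = rep(0.4, 100), f_b = rep(0.6, 100)))
  row <- posterior_summary(ch)[1, ]
  expect_equal(row$mean, 0.4)
  expect_equal(row$median, 0.4)
  expect_equal(row$sd, 0)
  expect_equal(c(row$ci68_lo, row$ci68_hi), c(0.4, 0.4))
})

test_that("summaries are invariant to chain-order permutation", {
  set.seed(42)
  v <- rbeta(5000, 2, 5)
  ch1 <- fake_chain(tibble::tibble(f_a = v, f_b = 1 - v))
  ch2 <- fake_chain(tibble::tibble(f_a = sample(v), f_b = 1 - sample(v)))
  expect_equal(posterior_summary(ch1)[1, -1], posterior_summary(ch2)[1, -1])
})

test_that("two-source mixing chains are perfectly anti-correlated", {
  set.seed(43)
  v <- runif(2000)
  ch <- fake_chain(tibble::tibble(f_a = v, f_b = 1 - v))
  cm <- correlation_matrix(ch)
  expect_equal(cm["f_a", "f_b"], -1)
  expect_equal(diag(cm), c(f_a = 1, f_b = 1))
  expect_equal(cm, t(cm))
})

test_that("independent columns decorrelate and zero variance is undefined", {
  set.seed(44)
  ch <- fake_chain(tibble::tibble(f_a = runif(1e5), r_r = runif(1e5)))
  expect_lt(abs(correlation_matrix(ch)["f_a", "r_r"]), 0.02)
  chz <- fake_chain(tibble::tibble(f_a = runif(100), r_r = rep(0.5, 100)))
  cm <- correlation_matrix(chz)
  expect_true(is.na(cm["f_a", "r_r"]))
  expect_true(is.na(cm["r_r", "r_r"]))
})

test_that("correlations in the 2D mixing fixture are all negative", {
  cs <- load_case("2d_mixing")
  ch <- run_chain(cs$model, cs$samples[1, ], chain_length = 10000,
                  burn_in = 500, seed = 45)
  cm <- correlation_matrix(ch)
  expect_true(all(cm[upper.tri(cm)] < 0))
})

test_that("z-scores vanish inside the spread band and scale as a z otherwise", {
  set.seed(46)
  n <- 400
  mu <- rnorm(n, 10.2, 0.5)
  ch <- fake_chain(tibble::tibble(f_a = runif(n), mu_I1 = mu,
                                  spread_I1 = rep(1.5, n)),
                   signatures = "I1", x = 10)
  zs <- z_scores(ch)
  expect_equal(zs$z, 0)                       # |x - mu_bar| < 1.5
  expect_equal(zs$rejection_probability, 0)
  # zero spread: z = |x - mu_bar| / (sd / sqrt(n)), checked against a case
  # engineered to give z = 1
  mu2 <- as.vector(scale(mu)) * 0.5 + 10 + 0.5 / sqrt(n)
  ch2 <- fake_chain(tibble::tibble(f_a = runif(n), mu_I1 = mu2,
                                   spread_I1 = rep(0, n)),
                    signatures = "I1", x = 10)
  expect_equal(z_scores(ch2)$z, 1, tolerance = 1e-10)
  # far outside the band, z grows with chain length
  mk <- function(n) fake_chain(tibble::tibble(f_a = runif(n),
                                              mu_I1 = rnorm(n, 15, 0.5),
                                              spread_I1 = rep(1, n)),
                               signatures = "I1", x = 10)
  expect_gt(z_scores(mk(4000))$z, z_scores(mk(250))$z)
})

test_that("z-score bands act per signature independently", {
  set.seed(47)
  n <- 300
  ch <- fake_chain(tibble::tibble(
    f_a = runif(n),
    mu_I1 = rnorm(n, 10.5, 0.3), spread_I1 = rep(1, n),   # inside band
    mu_I2 = rnorm(n, 18, 0.3), spread_I2 = rep(1, n)),    # far outside
    signatures = c("I1", "I2"), x = c(10, 10))
  zs <- z_scores(ch)
  expect_equal(zs$z[1], 0)
  expect_gt(zs$z[2], 3)
})

test_that("z-scores convert to the standard two-sided probabilities", {
  expect_equal(z_to_probability(0), 0)
  expect_equal(round(z_to_probability(2), 4), 0.9545)
  expect_equal(round(z_to_probability(3), 4), 0.9973)
  expect_error(z_to_probability(-1))
})

test_that("two-chain comparison flags agreement and disagreement correctly", {
  cs <- load_case("2d_mixing")
  ch1 <- run_chain(cs$model, cs$samples[1, ], chain_length = 5000,
                   burn_in = 500, seed = 48)
  ch1b <- run_chain(cs$model, cs$samples[1, ], chain_length = 5000,
                    burn_in = 500, seed = 48)
  same <- two_chain_convergence(ch1, ch1b)
  expect_equal(same$z, rep(0, nrow(same)))
  expect_true(attr(same, "converged"))
  # independent seeds converge to the same distribution
  ch2 <- run_chain(cs$model, cs$samples[1, ], chain_length = 5000,
                   burn_in = 500, seed = 49)
  indep <- two_chain_convergence(ch1, ch2)
  expect_true(attr(indep, "converged"))
  # chains from different measurements disagree
  other <- cs$samples[1, ]
  other$I1 <- 14
  ch3 <- run_chain(cs$model, other, chain_length = 5000, burn_in = 500,
                   seed = 50)
  expect_false(attr(two_chain_convergence(ch1, ch3), "converged"))
})
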