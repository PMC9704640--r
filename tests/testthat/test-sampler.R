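test_that("proposals live on the simplex and inside prior bounds", {
  model <- iso_model(tibble::tibble(
    name = c("A", "B", "C"), mode = "point",
    I1_mean = c(0, 10, 20), I1_sd = 1),
    aux_vars = tibble::tibble(name = "r", lo = 0.2, hi = 0.8),
    equation = "f1*S1 + f2*S2 + f3*S3")
  set.seed(1)
  pr <- propose_states(model, 1e5)
  fm <- as.matrix(pr[paste0("f_", c("A", "B", "C"))])
  expect_lt(max(abs(rowSums(fm) - 1)), 1e-12)
  # flat-Dirichlet component means are 1/3
  expect_equal(unname(colMeans(fm)), rep(1 / 3, 3), tolerance = 0.005)
  expect_true(all(pr$r_r > 0.2 & pr$r_r < 0.8))

  # single source: degenerate simplex
  m1 <- iso_model(tibble::tibble(name = "only", mode = "point",
                                 I1_mean = 5, I1_sd = 1))
  expect_true(all(propose_states(m1, 100)$f_only == 1))
})

test_that("threshold acceptance follows L >= alpha * T with running threshold", {
  # first iteration: T = 0 accepts any positive likelihood
  expect_true(threshold_accept(1e-12, 0, 0.99)$accepted)
  # L >= T accepts for every alpha
  for (a in c(0, 0.3, 1)) expect_true(threshold_accept(2, 2, a)$accepted)
  # acceptance updates T; rejection leaves it
  expect_equal(threshold_accept(0.7, 1, 0.5)$T, 0.7)
  expect_equal(threshold_accept(0.2, 1, 0.5)$T, 1)
  expect_error(threshold_accept(-1, 0, 0.5), "non-negative")
  # frequency: P(accept) = L / T when L < T
  set.seed(2)
  acc <- vapply(runif(1e4), function(a) threshold_accept(0.5, 1, a)$accepted,
                TRUE)
  expect_equal(mean(acc), 0.5, tolerance = 0.02)
})

test_that("chains are seed-reproducible and conserve the simplex", {
  cs <- load_case("2d_mixing")
  ch1 <- run_chain(cs$model, cs$samples[1, ], chain_length = 3000,
                   burn_in = 300, seed = 5)
  ch2 <- run_chain(cs$model, cs$samples[1, ], chain_length = 3000,
                   burn_in = 300, seed = 5)
  expect_identical(ch1$entries, ch2$entries)
  fm <- as.matrix(ch1$entries[paste0("f_", cs$model$source_names)])
  expect_lt(max(abs(rowSums(fm) - 1)), 1e-12)
  expect_true(all(ch1$entries$likelihood > 0))
})

test_that("a single source consistent with the data yields a constant chain", {
  m1 <- iso_model(tibble::tibble(name = "only", mode = "point",
                                 I1_mean = 5, I1_sd = 1))
  ch <- run_chain(m1, one_sig_sample(5, 0.5), chain_length = 500,
                  burn_in = 50, seed = 6)
  expect_true(all(ch$entries$f_only == 1))
})

test_that("an unreachable measurement raises the model-cannot-reach error", {
  m <- two_source_point_model()
  # likelihood underflows to exactly 0 everywhere: x is ~1000 sd away
  expect_error(
    run_chain(m, one_sig_sample(1e5, 0.1), chain_length = 100,
              burn_in = 0, max_iterations = 2000, seed = 7),
    class = "isomix_unreachable_error")
})

test_that("exhausting the iteration cap returns a flagged shorter chain", {
  m <- two_source_point_model()
  expect_warning(
    ch <- run_chain(m, one_sig_sample(), chain_length = 4000, burn_in = 0,
                    max_iterations = 4500, seed = 8, block_size = 1000),
    "stopped")
  expect_true(ch$exhausted)
  expect_lt(nrow(ch$entries), 4000)
  expect_gt(nrow(ch$entries), 0)
})

test_that("threshold and independence-Metropolis means agree on the 2D fixture", {
  cs <- load_case("2d_mixing")
  cht <- run_chain(cs$model, cs$samples[1, ], chain_length = 30000,
                   burn_in = 1000, seed = 9)
  chm <- run_chain(cs$model, cs$samples[1, ], chain_length = 30000,
                   burn_in = 1000, seed = 10, method = "metropolis")
  mt <- tidy(cht)$mean
  mm <- tidy(chm)$mean
  expect_lt(max(abs(mt - mm)), 0.02)
})

test_that("1D threshold-chain marginals match the dense-grid posterior (range mode)", {
  # range-mode two-source problem: the posterior is a smoothed plateau and
  # the grid oracle uses its own erf expression
  model <- two_source_range_model()
  oracle <- grid_posterior_1d(function(f1) {
    mu <- f1 * 2 + (1 - f1) * 20
    D <- f1 * 2 + (1 - f1) * 4
    erf1 <- function(t) 2 * pnorm(t * sqrt(2)) - 1
    max(erf1((11 - mu + D) / (0.1 * sqrt(2))) -
          erf1((11 - mu - D) / (0.1 * sqrt(2))), 0)
  })
  ch <- run_chain(model, one_sig_sample(), chain_length = 1e5,
                  burn_in = 1000, seed = 12)
  ks <- ks_against_grid(chain_entries(ch)$f_S1, oracle)
  expect_lt(ks, 0.02)
})

test_that("metropolis marginals match the grid posterior for point-mode sources", {
  model <- two_source_point_model()
  oracle <- grid_posterior_1d(function(f1) {
    mu <- f1 * 2 + (1 - f1) * 20
    sg <- sqrt(0.1^2 + f1^2 * 4 + (1 - f1)^2 * 16)
    dnorm(11, mu, sg)
  })
  ch <- run_chain(model, one_sig_sample(), chain_length = 1e5,
                  burn_in = 1000, seed = 13, method = "metropolis")
  ks <- ks_against_grid(chain_entries(ch)$f_S1, oracle)
  expect_lt(ks, 0.02)
})

test_that("batches are deterministic, independent per sample, and error-tolerant", {
  cs <- load_case("nitrate_case1")
  b1 <- run_batch(cs$model, cs$samples, seed = 14, chain_length = 1500,
                  burn_in = 200)
  b2 <- run_batch(cs$model, cs$samples, seed = 14, chain_length = 1500,
                  burn_in = 200)
  expect_identical(b1$x1$entries, b2$x1$entries)
  expect_identical(names(b1), c("x1", "x2"))
  # identical samples with the same derived seed give identical chains
  twin <- cs$samples[c(1, 1), ]
  twin$id <- c("a", "b")
  ba <- run_batch(cs$model, twin, seed = 15, chain_length = 800, burn_in = 100)
  bb <- run_batch(cs$model, twin, seed = 15, chain_length = 800, burn_in = 100)
  expect_identical(ba$a$entries, bb$a$entries)
  # empty batch
  expect_length(run_batch(cs$model, cs$samples[0, ], seed = 1), 0)
  # a failing sample is reported, not fatal
  bad <- cs$samples
  bad$d15N[2] <- 1e6
  # the tight iteration cap makes the good sample exhaust (warning) and the
  # impossible one fail outright
  bm <- suppressWarnings(run_batch(cs$model, bad, seed = 16,
                                   chain_length = 500, burn_in = 50,
                                   max_iterations = 2000))
  expect_s3_class(bm$x1, "iso_chain")
  expect_s3_class(bm$x2, "error")
})
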