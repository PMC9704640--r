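test_that("mixing is the fraction-weighted source mean and stays in the hull", {
  expect_equal(mix_mu0(c(0.2, 0.6, 0.2), c(5.0, -16.5, 3.0)), -8.3)
  expect_equal(mix_mu0(c(1, 0, 0), c(7, -3, 12)), 7)
  expect_equal(unname(mix_mu0(rep(1 / 3, 3), c(0, 10, 20))), 10)

  # convex-combination property over random simplex points and 2-signature
  # sources
  set.seed(42)
  S <- matrix(stats::runif(6, -30, 30), 3, 2)
  for (k in 1:25) {
    f <- as.vector(isomix:::rdirichlet(1, c(1, 1, 1)))
    mu <- mix_mu0(f, S)
    expect_true(all(mu >= apply(S, 2, min) - 1e-12))
    expect_true(all(mu <= apply(S, 2, max) + 1e-12))
  }
  expect_error(mix_mu0(c(0.5, 0.5), matrix(1, 3, 2)), "source rows")
  expect_error(mix_mu0(c(0.7, 0.7), c(1, 2)), "sum to 1")
})

test_that("fractionation shifts return mu0 exactly at their no-process point", {
  mu0 <- c(-8.3, 8.1)
  expect_equal(open_system_shift(mu0, c(-5, -3), 1), mu0)          # residual
  expect_equal(open_system_shift(mu0, c(-5, -3), 0, "reduced"), mu0)
  expect_equal(rayleigh_shift(mu0, c(-5, -3), 1), mu0)
  expect_equal(equilibrium_shift(mu0, c(8.6, 0), 0), mu0)
  expect_equal(craig_gordon_mu(mu0, c(1.8, 1.6), c(5.6, 0.3), 0), mu0)
})

test_that("open-system conventions give the printed worked values", {
  expect_equal(open_system_shift(10, -5, 0.5), 12.5)
  shifted <- open_system_shift(c(-8.3, 8.1), c(-15.9, -8.0), 0.6, "reduced")
  expect_equal(round(shifted, 1), c(1.2, 12.9))
  expect_equal(shifted[1], 1.24)
  expect_error(open_system_shift(10, -5, 1.2), class = "isomix_domain_error")
})

test_that("Rayleigh shift reproduces the synthetic N2O nitrogen values", {
  mu0 <- 0.9 * (-47.6) + 0.1 * (-37.8)
  expect_equal(round(rayleigh_shift(mu0, -7.1, 0.8), 1), -45.0)
  expect_equal(round(rayleigh_shift(mu0, -7.1, 0.2), 1), -35.2)
  expect_error(rayleigh_shift(10, -5, 0), class = "isomix_domain_error")
  expect_error(rayleigh_shift(10, -5, -0.1), class = "isomix_domain_error")
})

test_that("equilibrium shift interpolates to the endpoint", {
  expect_equal(equilibrium_shift(12.65, 8.6, 1, 0.25), 11.6375)
  expect_equal(equilibrium_shift(c(5, 7), c(1, 2), 1), c(1, 2))
  expect_error(equilibrium_shift(5, 1, 0.9, 1.2), class = "isomix_domain_error")
})

test_that("Craig-Gordon enrichment matches the lake-water worked example", {
  expect_equal(round(craig_gordon_mu(-5.0, 1.7881, 5.6063, 0.2206), 1), -2.0)
  expect_equal(round(craig_gordon_mu(-34, 1.5824, 0.2946, 0.2248), 0), -25)
  # monotone toward D for A > 0
  rs <- seq(0, 2, length.out = 21)
  mus <- vapply(rs, function(r) craig_gordon_mu(-5, 1.7881, 5.6063, r), 0)
  expect_true(all(diff(mus) > 0))
  expect_true(all(mus < 5.6063))
  expect_error(craig_gordon_mu(0, -2, 1, 0.5), class = "isomix_domain_error")
})

test_that("nitrite model applies the 0.7:0.3 sink weights and O equilibration", {
  mids <- rbind(c(4.3, -13.3), c(18.4, 68.9), c(18.4, 5.4))  # d18O, d15N
  f <- c(0.5, 0.1, 0.4)
  # nitrogen: no equilibration
  expect_equal(nitrite_mu(f, mids[, 2, drop = FALSE], A = -10, B = 13, C = 0),
               2.4 + 7 - 3.9)
  # oxygen: C = 0.25 pulls toward 8.6
  expect_equal(nitrite_mu(f, mids[, 1, drop = FALSE], A = -4, B = 5, C = 0.25),
               (11.35 + 2.8 - 1.5) * 0.75 + 8.6 * 0.25)
  # C = 0, A = B = 0 reduces to plain mixing
  expect_equal(nitrite_mu(f, mids, A = 0, B = 0, C = 0), mix_mu0(f, mids))
  expect_error(nitrite_mu(f, mids, 0, 0, C = 1.5),
               class = "isomix_domain_error")
})

test_that("N2O model composes mixing with Rayleigh reduction", {
  S <- rbind(c(-47.6), c(-56.9), c(-37.8), c(-56.6))
  expect_equal(round(n2o_mu(c(0.9, 0, 0.1, 0), S, -7.1, 0.8), 1), -45.0)
  f <- rep(0.25, 4)
  expect_equal(n2o_mu(f, S, -7.1, 0.5), mean(S) + (-7.1) * log(0.5))
  expect_equal(n2o_mu(f, S, -7.1, 1), mix_mu0(f, S))
})

test_that("nitrification recalculation reproduces the recalculated end-members", {
  fert <- recalc_nitrification_source(0.5, -17.0, 5.0, 23.5)
  expect_equal(unname(round(fert, 1)), c(-16.5, 11.2))
  man <- recalc_nitrification_source(20.0, -17.0, -5.0, 23.5)
  expect_equal(unname(round(man, 1)), c(3.0, 4.5))
  expect_equal(unname(recalc_nitrification_source(0, 0, 0, 0)), c(0, 0))
})

test_that("expression equations match the builtins on a grid", {
  src <- tibble::tibble(name = c("S1", "S2", "S3"), mode = "range",
                        I1_mean = c(0, 10, 20), I1_halfrange = c(1, 2, 2),
                        I2_mean = c(0, 30, 0), I2_halfrange = c(1, 2, 1))
  aux <- tibble::tibble(name = "A", I1_mean = -5, I1_sd = 1,
                        I2_mean = -5, I2_sd = 1)
  m_builtin <- iso_model(src, aux, aux_vars = "r", equation = "rayleigh")
  m_expr <- iso_model(src, aux, aux_vars = "r",
                      equation = "f1*S1 + f2*S2 + f3*S3 + A*ln(r)")
  m_mix <- iso_model(src[, ], equation = "mixing")
  m_mix_expr <- iso_model(src, equation = "f1*S1 + f2*S2 + f3*S3")

  set.seed(7)
  for (k in 1:100) {
    f <- as.vector(isomix:::rdirichlet(1, c(1, 1, 1)))
    r <- stats::runif(1, 0.05, 1)
    pb <- predict_mu(m_builtin, f, r)
    pe <- predict_mu(m_expr, f, r)
    expect_equal(pe$mu, pb$mu, tolerance = 1e-9)
    expect_equal(pe$sigma, pb$sigma, tolerance = 1e-6)
    expect_equal(pe$spread, pb$spread, tolerance = 1e-6)
    expect_equal(predict_mu(m_mix_expr, f)$mu, predict_mu(m_mix, f)$mu,
                 tolerance = 1e-9)
  }
})

test_that("pre-mixing fractionation of a single source is expressible", {
  src <- tibble::tibble(name = c("S1", "S2", "S3"), mode = "point",
                        I1_mean = c(-40, -10, 5), I1_sd = c(1, 1, 1))
  aux <- tibble::tibble(name = "A", I1_mean = -7, I1_sd = 0)
  m_expr <- iso_model(src, aux, aux_vars = "r",
                      equation = "f1*(S1 + A*ln(r)) + f2*S2 + f3*S3")
  m_builtin <- iso_model(src, aux, aux_vars = "r",
                         equation = "rayleigh_source1")
  f <- c(0.5, 0.3, 0.2)
  expect_equal(predict_mu(m_expr, f, 0.4)$mu, predict_mu(m_builtin, f, 0.4)$mu,
               tolerance = 1e-9)
  # hand value: f1*(S1 + A ln r) + ...
  expect_equal(predict_mu(m_expr, f, 0.4)$mu,
               0.5 * (-40 + -7 * log(0.4)) + 0.3 * -10 + 0.2 * 5)
})

test_that("expression parsing rejects unknown or unsafe tokens", {
  expect_error(parse_model_equation("f1*S1 + q", m = 2),
               class = "isomix_parse_error")
  expect_error(parse_model_equation("system('ls')", m = 1),
               class = "isomix_parse_error")
  expect_error(parse_model_equation("f1*(S1", m = 1),
               class = "isomix_parse_error")
  expect_error(parse_model_equation("f1*S1 + A*ln(r)", m = 1),
               class = "isomix_parse_error")  # undeclared A and r
})
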