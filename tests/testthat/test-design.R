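test_that("zero association with homogeneous margins gives the product measure", {
  d <- nua_design(5, 100, rep(0, 4), rep(0.2, 5))
  expect_true(d$converged)
  expect_equal(d$pi, matrix(0.04, 5, 5), tolerance = 1e-10)
  expect_equal(d$lambda, rep(0, 5), tolerance = 1e-10)
})

test_that("symmetric scenarios give palindromic lambda and diagonal-heavy pi", {
  d <- nua_design(5, 100, rep(log(3), 4), rep(0.2, 5))
  expect_equal(d$lambda, rev(d$lambda), tolerance = 1e-8)
  expect_gt(d$pi[1, 1], d$pi[1, 5])
  expect_equal(d$pi, t(d$pi), tolerance = 1e-12)
  expect_equal(sum(d$lambda), 0, tolerance = 1e-10)
  expect_equal(sum(d$pi), 1, tolerance = 1e-10)
})

test_that("solved designs reproduce target margins to solver tolerance", {
  margin_sets <- list(
    rep(0.2, 5),
    c(.05, .24, .24, .24, .23),
    c(.24, .05, .24, .24, .23),
    c(.05, .30, .30, .30, .05),
    c(.05, .15, .40, .30, .10))
  for (m in margin_sets) {
    d <- nua_design(5, 150, rep(log(3), 4), m)
    expect_true(d$converged)
    expect_lt(max(abs(rowSums(d$pi) - m)), 1e-8)
    expect_lt(max(abs(colSums(d$pi) - m)), 1e-8)
    expect_lte(d$residual, 1e-10)
    expect_true(all(d$pi > 0))
  }
})

test_that("the solved surface and the model module agree on the association", {
  configs <- list(rep(log(3), 4), c(0, log(3), log(3), log(3)),
                  c(log(16), log(3), log(3), log(16)),
                  c(0, 0, log(2), log(2)))
  for (b in configs) {
    d <- nua_design(5, 100, b, rep(0.2, 5))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(empirical_tau(d$pi, i, j), tau_from_betas(i, j, b),
                   tolerance = 1e-6)
    }
  }
})

test_that("fitting the generating grouping to expected counts recovers beta", {
  b <- c(0, 0, log(3), log(3))
  d <- nua_design(5, 1, b, rep(0.2, 5))
  # exact expected counts (unrounded) through the fitting core
  part <- nua_partition(5, "12,23|34,45")
  X <- nua_design_matrix(part)
  core <- nuapower:::fit_poisson_core(as.vector(d$pi * 1e6), X)
  expect_true(core$converged)
  expect_equal(unname(core$theta[10:11]), c(0, log(3)), tolerance = 1e-4)
})

test_that("the probability surface is invariant to the sample size", {
  b <- c(log(2), log(3), log(3), log(2))
  d1 <- nua_design(5, 50, b, rep(0.2, 5))
  d2 <- nua_design(5, 5000, b, rep(0.2, 5))
  expect_equal(d1$pi, d2$pi, tolerance = 1e-10)
  d3 <- design_with_n(d1, 5000)
  expect_equal(d3$mu, d2$mu, tolerance = 1e-8)
})

test_that("warm starts walk the odds-ratio grid and agree with cold solves", {
  ks <- c(1:10, 12, 14, 16)
  configs <- lapply(ks, function(K) c(log(K), rep(log(3), 3)))
  path <- warm_start_path(5, 100, rep(0.2, 5), configs)
  expect_length(path, 13L)
  expect_true(all(vapply(path, `[[`, logical(1), "converged")))

  # single-element path is an ordinary solve
  single <- warm_start_path(5, 100, rep(0.2, 5), configs[5])
  cold <- nua_design(5, 100, configs[[5]], rep(0.2, 5))
  expect_equal(single[[1]]$pi, cold$pi, tolerance = 1e-10)

  # reversing the grid reaches the same fixed points
  rev_path <- warm_start_path(5, 100, rep(0.2, 5), rev(configs))
  expect_equal(rev_path[[13]]$pi, path[[1]]$pi, tolerance = 1e-8)
  expect_equal(rev_path[[1]]$pi, path[[13]]$pi, tolerance = 1e-8)
})

test_that("margin validation is enforced and near-degenerate margins warn", {
  expect_error(nua_design(5, 100, rep(0, 4), c(.2, .2, .2, .2, .3)), "sum to 1")
  expect_error(nua_design(5, 100, rep(0, 4), c(0, .3, .3, .3, .1)), "positive")
  expect_warning(nua_design(5, 100, rep(0, 4), c(5e-4, .2995, .3, .3, .1)),
                 "1e-3")
})

test_that("multinomial draws conserve the total and honour the seed", {
  d <- nua_design(5, 87, rep(log(3), 4), rep(0.2, 5))
  set.seed(99); t1 <- sample_table(d)
  expect_equal(sum(t1), 87)
  expect_true(all(t1 >= 0) && all(t1 == round(t1)))
  set.seed(99); t2 <- sample_table(d)
  expect_identical(t1, t2)

  tabs <- simulate(d, nsim = 4, seed = 123)
  expect_length(tabs, 4L)
  expect_true(all(vapply(tabs, sum, numeric(1)) == 87))
})

test_that("cell frequencies match the design probabilities on average", {
  d <- nua_design(5, 100, rep(log(3), 4), rep(0.2, 5))
  set.seed(7)
  draws <- sample_table(d, n = 5000)
  m11 <- mean(vapply(draws, function(t) t[1, 1], numeric(1)))
  exp11 <- 100 * d$pi[1, 1]
  mc_se <- sqrt(100 * d$pi[1, 1] * (1 - d$pi[1, 1]) / 5000)
  expect_lt(abs(m11 - exp11), 4 * mc_se)
})

test_that("design dumps round-trip through disk", {
  d <- nua_design(5, 120, c(0, log(3), log(3), log(3)), c(.05, .24, .24, .24, .23))
  path <- tempfile(fileext = ".csv")
  write_design(d, path)
  back <- read_design(path)
  expect_equal(back$pi, d$pi, tolerance = 1e-12)
  expect_equal(back$mu, d$mu, tolerance = 1e-10)
  expect_equal(back$N, d$N)
})
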