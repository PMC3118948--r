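test_that("independence fit on a diagonal 2x2 table gives the hand-computed deviance", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  fit <- nua(tab, "independence")
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted), matrix(5, 2, 2), tolerance = 1e-8)
  expect_equal(fit$g_squared, 40 * log(2), tolerance = 1e-8)
})

test_that("residual degrees of freedom follow the cells-minus-parameters count", {
  tab3 <- matrix(c(20, 6, 1, 5, 19, 6, 2, 4, 18), 3, 3)
  expect_equal(nua(tab3, "full")$df_residual, 2L)           # 9 - 5 - 2
  expect_equal(nua(tab3, "uniform")$df_residual, 3L)        # 9 - 5 - 1
  expect_equal(nua(tab3, "independence")$df_residual, 4L)   # 9 - 5

  tab5 <- random_agreement_table(5, N = 300, seed = 5)
  expect_equal(nua(tab5, "uniform")$df_residual, 15L)       # 25 - 9 - 1
  expect_equal(nua(tab5, "full")$df_residual, 12L)          # 25 - 9 - 4
})

test_that("fitting noiseless expected counts recovers the generating parameters", {
  # uniform truth
  tab <- expected_table(rep(log(3), 4), rep(0.2, 5))
  fit <- nua(tab, "uniform")
  expect_true(fit$converged)
  expect_equal(unname(fit$betas), log(3), tolerance = 1e-3)

  # grouped truth, fitted with the generating grouping
  tab2 <- expected_table(c(0, 0, log(3), log(3)), rep(0.2, 5))
  fit2 <- nua(tab2, "12,23|34,45")
  expect_equal(unname(fit2$betas), c(0, log(3)), tolerance = 1e-3)
})

test_that("fitted margins reproduce observed margins for every converged fit", {
  for (seed in 1:5) {
    I <- sample(3:6, 1)
    tab <- random_agreement_table(I, N = 150, seed = seed)
    for (spec in list("independence", "uniform", "full")) {
      fit <- nua(tab, spec)
      if (!fit$converged) next
      expect_lt(max(abs(rowSums(fit$fitted) - rowSums(tab))) /
                  max(rowSums(tab)), 1e-6)
      expect_lt(max(abs(colSums(fit$fitted) - colSums(tab))) /
                  max(colSums(tab)), 1e-6)
      expect_equal(sum(fit$fitted), sum(tab), tolerance = 1e-8)
      expect_true(all(fit$fitted > 0))
    }
  }
})

test_that("fit agrees with an independent generic Poisson regression oracle", {
  for (seed in 1:4) {
    for (I in c(4, 5)) {
      tab <- random_agreement_table(I, N = 250, seed = seed + 10 * I)
      for (spec in list("uniform", "full", "independence")) {
        part <- nua_partition(I, spec)
        fit <- nua(tab, part)
        skip_if_not(fit$converged)
        oracle <- glm_oracle(tab, part)
        expect_equal(as.vector(fit$fitted), oracle$fitted, tolerance = 1e-6)
        expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
      }
    }
  }
})

test_that("refining a partition never increases the deviance", {
  chains <- list(
    c("independence", "uniform", "12|2345", "full"),
    c("uniform", "12,23|34,45", "full"),
    c("uniform", "12,45|23,34", "full"))
  for (seed in 1:4) {
    tab <- random_agreement_table(5, N = 120, seed = 100 + seed)
    for (chain in chains) {
      g2 <- vapply(chain, function(s) nua(tab, s)$g_squared, numeric(1))
      expect_true(all(diff(g2) <= 1e-8))
    }
  }
})

test_that("merging all classes reproduces the uniform fit exactly", {
  tab <- random_agreement_table(5, N = 200, seed = 7)
  f1 <- nua(tab, "uniform")
  f2 <- nua(tab, nua_partition(5, list(1:4)))
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("degenerate tables are reported, not raised", {
  tab <- matrix(c(5, 2, 0, 3, 6, 0, 2, 4, 0), 3, 3)  # empty column 3
  fit <- nua(tab, "uniform")
  expect_false(fit$converged)
  expect_match(fit$message, "empty")

  expect_error(nua(matrix(1:6, 2, 3)), "square")
  expect_error(nua(matrix(c(-1, 2, 2, 1), 2, 2)), "non-negative")
  expect_error(nua(matrix(0, 3, 3)), "at least one")
})

test_that("model accessors are coherent", {
  tab <- random_agreement_table(5, N = 200, seed = 9)
  fit <- nua(tab, "uniform")
  expect_equal(deviance(fit), fit$g_squared)
  expect_equal(df.residual(fit), 15L)
  expect_equal(attr(logLik(fit), "df"), 10L)
  expect_length(coef(fit), 12L)  # mu + 5 + 5 + 1 (centred effects reported)
  expect_equal(sum(residuals(fit, "pearson") * sqrt(fit$fitted)),
               sum(tab - fit$fitted), tolerance = 1e-8)
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3L)
  expect_true(all(vapply(sims, sum, numeric(1)) == fit$N))
})
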