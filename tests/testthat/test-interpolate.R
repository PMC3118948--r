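panel_b <- function() {
  read_power_table(system.file("extdata", "table3_panel_b.csv",
                               package = "nuapower"))
}

test_that("interpolating the tabulated grid reproduces the worked example", {
  tab <- panel_b()
  p <- interp_power_at_beta(tab, 2.25)
  expect_equal(unname(round_display(p)), c(.34, .55, .73, .84, .91))
  # full-precision midpoints, before display rounding
  expect_equal(unname(p), c(.335, .55, .725, .84, .905), tolerance = 1e-12)
})

test_that("the required sample size uses unrounded interpolated powers", {
  tab <- panel_b()
  res <- required_n(tab, beta = 2.25, target = 0.80)
  # 150 + 50 * (0.80 - 0.725) / (0.84 - 0.725), not the 2-dp-rounded 181.82
  expect_equal(res$n_real, 182.61, tolerance = 0.01)
  expect_equal(res$n_integer, 183L)
})

test_that("interpolation endpoints are exact and degenerate queries behave", {
  tab <- panel_b()
  expect_equal(unname(interp_power_at_beta(tab, 2.20)),
               c(.32, .53, .69, .81, .89))
  expect_equal(unname(interp_power_at_beta(tab, 2.30)),
               c(.35, .57, .76, .87, .92))
  # midpoint of equal-valued rows returns the same values
  flat <- tab
  flat$power[2, ] <- flat$power[1, ]
  mid <- (flat$betas[1] + flat$betas[2]) / 2
  expect_equal(interp_power_at_beta(flat, mid),
               interp_power_at_beta(flat, flat$betas[1]))
  expect_error(interp_power_at_beta(tab, 5), "outside")
  expect_error(interp_power_at_beta(tab, -1), "outside")
})

test_that("required_n hits grid values exactly and refuses extrapolation", {
  tab <- panel_b()
  p <- interp_power_at_beta(tab, 2.30)
  res <- required_n(tab, 2.30, target = p[3])   # power at N = 150
  expect_equal(res$n_real, 150)
  expect_equal(res$n_integer, 150L)
  expect_error(required_n(tab, 1.10, target = 0.9999), "unattainable")
})

test_that("required_n is monotone in the target power", {
  tab <- panel_b()
  n70 <- required_n(tab, 2.25, 0.70)$n_real
  n80 <- required_n(tab, 2.25, 0.80)$n_real
  n90 <- required_n(tab, 2.25, 0.90)$n_real
  expect_true(n70 < n80 && n80 < n90)
})

test_that("power tables round-trip through CSV at full precision", {
  grid <- nua_power_grid("beta12", null_or = 3, ks = c(1, 3), ns = c(50, 100),
                         nsim = 50, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_power_table(grid, path)
  back <- read_power_table(path)
  expect_equal(unname(back$power), unname(grid$power), tolerance = 1e-12)
  expect_equal(back$betas, grid$betas, tolerance = 1e-12)
  expect_equal(back$ns, grid$ns)
  expect_equal(back$margins, grid$margins)
  expect_equal(back$hypothesis, grid$hypothesis)
  expect_equal(back$null_or, grid$null_or)
})

test_that("reading the packaged fixtures reproduces the printed values", {
  tab_a <- read_power_table(system.file("extdata", "table3_panel_a.csv",
                                        package = "nuapower"))
  expect_equal(unname(tab_a$power[1, ]), c(.34, .57, .74, .85, .92))
  expect_equal(unname(tab_a$power[3, "N250"]), .05)   # null row
  expect_equal(tab_a$or, c(1:10, 12, 14, 16))
  # the printed DD column is 1 - 1/OR at ~2 decimals (mixed rounding in print)
  expect_lt(max(abs(tab_a$dd - (1 - 1 / tab_a$or))), 0.01)
  expect_equal(tab_a$null_or, 3)
})

test_that("a missing DD column is recomputed from the odds ratio", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("beta,OR,N50,N100",
               "0.00,1,0.30,0.50",
               "1.10,3,0.05,0.05",
               "2.30,10,0.40,0.60"), path)
  tab <- read_power_table(path)
  expect_equal(tab$dd, 1 - 1 / c(1, 3, 10))
})

test_that("malformed power tables are rejected with a clear message", {
  p1 <- tempfile(); writeLines(c("x,y", "1,2"), p1)
  expect_error(read_power_table(p1), "header|columns")
  p2 <- tempfile(); writeLines(c("beta,OR,N100,N50", "0,1,.3,.2"), p2)
  expect_error(read_power_table(p2), "increasing")
})
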