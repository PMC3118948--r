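# one simulate-fit-test replicate; failures are data, not exceptions
run_replicate <- function(design, X_null, X_alt, ddf, alpha) {
  tab <- sample_table(design)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return("failed")
  y <- as.vector(tab)
  f0 <- fit_poisson_core(y, X_null)
  f1 <- fit_poisson_core(y, X_alt)
  if (!f0$converged || !f1$converged) return("failed")
  g0 <- 2 * sum(ifelse(y > 0, y * log(y / f0$mu), 0))
  g1 <- 2 * sum(ifelse(y > 0, y * log(y / f1$mu), 0))
  p <- stats::pchisq(max(g0 - g1, 0), ddf, lower.tail = FALSE)
  if (p < alpha) "significant" else "not_significant"
}

#' Monte-Carlo power (or type-I error) of a UA-vs-NUA likelihood-ratio test
#'
#' Repeatedly draws multinomial agreement tables from a simulation design,
#' fits the null and alternative association models to each, and applies the
#' chi-squared likelihood-ratio test on the G-squared difference. The
#' estimate is the proportion of significant tests among converged
#' replicates; replicates in which either fit fails (typically an empty
#' observed row or column at small N) are counted and excluded from the
#' denominator. When the design was generated under the null partition the
#' estimate is the empirical type-I error.
#'
#' Per-replicate seeds are drawn up front from the master seed, so results
#' are reproducible and independent of evaluation order.
#'
#' @param design a converged [nua_design()]: the data-generating truth.
#' @param null null-hypothesis partition (default `"uniform"`, the UA model).
#' @param alt alternative partition (a NUA grouping in which `null` is
#'   nested); anything accepted by [nua_partition()].
#' @param alpha significance level (default 0.05).
#' @param nsim number of replicates (default 2000).
#' @param seed master integer seed.
#' @return Object of class `"nua_power"`: list with `p_hat`, `mc_se`
#'   (binomial Monte-Carlo standard error), `n_significant`, `n_converged`,
#'   `n_failed`, plus the scenario (`design`, partitions, `alpha`, `nsim`,
#'   `seed`, `delta_df`).
#' @examples
#' d <- nua_design(5, 250, c(0, log(3), log(3), log(3)), rep(.2, 5))
#' nua_power(d, alt = "12|2345", nsim = 50, seed = 1)
#' @export
nua_power <- function(design, null = "uniform", alt, alpha = 0.05,
                      nsim = 2000L, seed = 1L) {
  stopifnot(inherits(design, "nua_design"))
  nsim <- as.integer(nsim)
  if (is.na(nsim) || nsim < 1L) stop("'nsim' must be a positive integer")
  if (!(alpha >= 0 && alpha <= 1)) stop("'alpha' must be in [0, 1]")
  I <- design$I
  if (!inherits(null, "nua_partition")) null <- nua_partition(I, null)
  if (!inherits(alt, "nua_partition")) alt <- nua_partition(I, alt)
  if (!is_nested(null, alt)) stop("'null' must be nested in 'alt'")
  X_null <- nua_design_matrix(null)
  X_alt <- nua_design_matrix(alt)
  ddf <- length(alt$groups) - length(null$groups)

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, nsim)
  out <- character(nsim)
  for (r in seq_len(nsim)) {
    set.seed(rep_seeds[r])
    out[r] <- run_replicate(design, X_null, X_alt, ddf, alpha)
  }
  n_fail <- sum(out == "failed")
  n_conv <- nsim - n_fail
  n_sig <- sum(out == "significant")
  p_hat <- if (n_conv > 0) n_sig / n_conv else NA_real_
  if (n_fail / nsim > 0.01)
    warning(sprintf("%.1f%% of replicates failed to converge", 100 * n_fail / nsim))
  structure(list(p_hat = p_hat,
                 mc_se = if (n_conv > 0) sqrt(p_hat * (1 - p_hat) / n_conv) else NA_real_,
                 n_significant = n_sig, n_converged = n_conv, n_failed = n_fail,
                 design = design, null = null, alt = alt, delta_df = ddf,
                 alpha = alpha, nsim = nsim, seed = seed),
            class = "nua_power")
}

#' @export
print.nua_power <- function(x, ...) {
  cat(sprintf(
    "Rejection rate %.4f (MC se %.4f) at alpha = %g; %d/%d replicates converged\n",
    x$p_hat, x$mc_se, x$alpha, x$n_converged, x$nsim))
  invisible(x)
}

# hypothesis label -> generating betas for tested odds ratio K, and the
# alternative grouping tested against the uniform null
hypothesis_scheme <- function(hypothesis, I = 5L) {
  if (I != 5L && hypothesis != "all_diff")
    stopifnot(I >= 3L)
  switch(hypothesis,
    beta12 = list(
      betas = function(K, b0) c(log(K), rep(b0, I - 2L)),
      alt = nua_partition(I, list(1L, 2:(I - 1L)))),
    beta12_23 = list(
      betas = function(K, b0) c(log(K), log(K), rep(b0, I - 3L)),
      alt = nua_partition(I, list(1:2, 3:(I - 1L)))),
    beta12_45 = list(
      betas = function(K, b0) c(log(K), rep(b0, I - 3L), log(K)),
      alt = nua_partition(I, list(c(1L, I - 1L), 2:(I - 2L)))),
    all_diff = list(
      betas = function(K, b0) c(log(K), rep(b0, I - 2L)),
      alt = nua_partition(I, "full")),
    stop("unknown hypothesis label '", hypothesis,
         "' (use beta12, beta12_23, beta12_45 or all_diff)")
  )
}

#' Power grid over tested odds ratios and sample sizes
#'
#' For one alternative-hypothesis pattern, estimates the rejection rate of
#' the UA-vs-NUA likelihood-ratio test for every combination of tested odds
#' ratio `K` and sample size `N`. The generating parameters set the varying
#' adjacent pairs to `log(K)` and the remaining pairs to `log(null_or)`; the
#' row with `K = null_or` is therefore the type-I error. Designs are solved
#' along the `K` grid with warm starts.
#'
#' Hypothesis labels (for a 5-category scale):
#' * `"beta12"`: pair (1,2) differs from the rest (delta df 1);
#' * `"beta12_23"`: pairs (1,2) and (2,3) differ from (3,4), (4,5) (delta df 1);
#' * `"beta12_45"`: extreme pairs (1,2), (4,5) differ from the middle
#'   (delta df 1);
#' * `"all_diff"`: all four parameters free (delta df 3).
#'
#' @param hypothesis one of the labels above.
#' @param null_or common odds ratio of the non-varying pairs (the null value;
#'   default 3).
#' @param ks vector of tested odds ratios (default `c(1:10, 12, 14, 16)`).
#' @param ns vector of sample sizes (default `c(50, 100, 150, 200, 250)`).
#' @param margins target marginal probabilities (default homogeneous).
#' @param I number of categories (default 5).
#' @param alpha significance level.
#' @param nsim replicates per cell.
#' @param seed master seed.
#' @return Object of class `"nua_power_table"`: list with the scenario
#'   metadata, `betas = log(ks)`, `or = ks`, `dd = 1 - 1/ks`, `ns`, and
#'   matrices `power`, `se`, `failed` (rows = K grid, columns = N grid).
#' @export
nua_power_grid <- function(hypothesis, null_or = 3, ks = c(1:10, 12L, 14L, 16L),
                           ns = c(50L, 100L, 150L, 200L, 250L),
                           margins = NULL, I = 5L, alpha = 0.05,
                           nsim = 2000L, seed = 1L) {
  scheme <- hypothesis_scheme(hypothesis, I)
  if (is.null(margins)) margins <- rep(1 / I, I)
  b0 <- log(null_or)
  configs <- lapply(ks, scheme$betas, b0 = b0)
  designs <- warm_start_path(I, ns[1], margins, configs)

  set.seed(seed)
  cell_seeds <- matrix(sample.int(.Machine$integer.max - 1L,
                                  length(ks) * length(ns)),
                       length(ks), length(ns))
  pw <- se <- fl <- matrix(NA_real_, length(ks), length(ns),
                           dimnames = list(paste0("K", ks), paste0("N", ns)))
  for (a in seq_along(ks)) {
    for (b in seq_along(ns)) {
      est <- nua_power(design_with_n(designs[[a]], ns[b]),
                       null = "uniform", alt = scheme$alt,
                       alpha = alpha, nsim = nsim, seed = cell_seeds[a, b])
      pw[a, b] <- est$p_hat
      se[a, b] <- est$mc_se
      fl[a, b] <- est$n_failed
    }
  }
  structure(list(hypothesis = hypothesis, null_or = null_or,
                 margins = margins, I = I, alpha = alpha, nsim = nsim,
                 seed = seed, or = as.numeric(ks), betas = log(ks),
                 dd = 1 - 1 / ks, ns = as.numeric(ns),
                 power = pw, se = se, failed = fl),
            class = "nua_power_table")
}

#' @export
print.nua_power_table <- function(x, digits = 2, ...) {
  cat(sprintf("Power of UA-vs-NUA tests: hypothesis %s, null OR %g, alpha %g, %d reps/cell\n",
              x$hypothesis, x$null_or, x$alpha, x$nsim))
  cat("margins:", round(x$margins, 3), "\n")
  df <- data.frame(beta = round_display(x$betas), OR = x$or,
                   DD = round_display(x$dd), round_display(x$power, digits),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
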