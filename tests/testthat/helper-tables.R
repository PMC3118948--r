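# shared fixture builders for the test suite

# draw a random I x I agreement table with diagonal-heavy structure so that
# association fits are well behaved
random_agreement_table <- function(I, N = 200, beta = log(3), seed = 1) {
  set.seed(seed)
  d <- nua_design(I, N, rep(beta, I - 1), rep(1 / I, I))
  sample_table(d)
}

# independent generic Poisson-regression oracle on the same design matrix
glm_oracle <- function(counts, partition) {
  X <- nua_design_matrix(partition)
  y <- as.vector(counts)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(),
                   control = list(epsilon = 1e-12, maxit = 100)))
  list(fitted = fit$fitted.values,
       loglik = sum(ifelse(y > 0, y * log(fit$fitted.values), 0)) -
         sum(fit$fitted.values) - sum(lgamma(y + 1)))
}

# expected-count table (rounded) from a solved design at large N
expected_table <- function(betas, margins, N = 1e6) {
  I <- length(margins)
  d <- nua_design(I, N, betas, margins)
  round(d$pi * N)
}
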