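#' Solve the cell-probability surface of a simulation design
#'
#' Given adjacent-pair association parameters `betas` and a target marginal
#' distribution (shared by the two raters: marginal homogeneity between
#' raters), finds the overall effect `mu` and shared category effects
#' `lambda[1..I]` such that the cell probabilities
#' `pi[i, j] = exp(mu + lambda[i] + lambda[j] - c(i, j)) / N`,
#' with `c(i, j) = (|i - j| / 2) * (beta[min] + ... + beta[max - 1])`,
#' reproduce the target margins exactly. The `I + 1` unknowns solve the
#' nonlinear system of `I` margin equations `sum_j pi[i, j] = margin[i]` plus
#' the normalisation `sum(lambda) = 0` (which keeps `mu` interpretable as the
#' overall effect). Because the system's row-margin equations sum to 1, the
#' solved `pi` is automatically a probability distribution, symmetric, with
#' identical row and column margins.
#'
#' A Newton iteration with the analytic Jacobian is used, warm-startable via
#' `init`; if Newton fails, a symmetric iterative-proportional-fitting
#' (Sinkhorn) pass on the kernel `exp(-c(i, j))` is used instead (valid
#' because kernel and margins are symmetric).
#'
#' @param I number of categories.
#' @param N sample size of tables later drawn from the design (`mu` absorbs
#'   `N`; the probability surface itself does not depend on it).
#' @param betas numeric vector of length `I - 1` of adjacent-pair
#'   log-odds-ratio parameters.
#' @param margins target marginal probabilities, length `I`, positive,
#'   summing to 1. Entries below `1e-3` are allowed but trigger a warning
#'   (they push the corresponding `lambda` to large negative values).
#' @param init optional warm start: list with `mu` and `lambda`.
#' @param tol residual tolerance (maximum absolute residual of the system).
#' @param maxit Newton iteration cap.
#' @return An object of class `"nua_design"`: list with `I`, `N`, `betas`,
#'   `margins`, solved `mu`, `lambda`, probability matrix `pi`, `residual`
#'   (max abs), `converged`, `method` (`"newton"` or `"ipf"`), `iterations`.
#' @examples
#' d <- nua_design(5, 100, rep(log(3), 4), rep(0.2, 5))
#' rowSums(d$pi)   # 0.2 each
#' @export
nua_design <- function(I, N, betas, margins, init = NULL,
                       tol = 1e-12, maxit = 200L) {
  I <- as.integer(I)
  stopifnot(I >= 2L, length(betas) == I - 1L, length(margins) == I)
  if (any(!is.finite(betas))) stop("'betas' must be finite")
  if (any(margins <= 0)) stop("margins must be strictly positive")
  if (abs(sum(margins) - 1) > 1e-8) stop("margins must sum to 1")
  margins <- margins / sum(margins)
  if (any(margins < 1e-3))
    warning("margin entries below 1e-3: lambda diverges toward -Inf, ",
            "convergence may be slow")
  N <- as.numeric(N)
  stopifnot(N >= 1)

  cmat <- assoc_cost_matrix(I, betas)

  pi_of <- function(mu, lambda)
    exp(mu + outer(lambda, lambda, "+") - cmat) / N

  if (is.null(init)) {
    mu0 <- log(N) + 2 * mean(log(margins))
    lam0 <- rep(0, I)
  } else {
    mu0 <- init$mu
    lam0 <- init$lambda
    stopifnot(length(lam0) == I)
  }

  resid_of <- function(mu, lambda) {
    pi <- pi_of(mu, lambda)
    c(rowSums(pi) - margins, sum(lambda))
  }

  mu <- mu0; lambda <- lam0
  f <- resid_of(mu, lambda)
  method <- "newton"; it <- 0L; ok <- FALSE
  while (it < maxit) {
    if (max(abs(f)) <= tol) { ok <- TRUE; break }
    it <- it + 1L
    pi <- pi_of(mu, lambda)
    s <- rowSums(pi)
    # Jacobian: rows 1..I are d(rowsum_i)/d(mu, lambda); last row is sum(lambda)
    J <- matrix(0, I + 1L, I + 1L)
    J[seq_len(I), 1L] <- s
    J[seq_len(I), 2L:(I + 1L)] <- pi + diag(s, I)
    J[I + 1L, 2L:(I + 1L)] <- 1
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    h <- 1
    repeat {
      mu_n <- mu - h * step[1L]
      lam_n <- lambda - h * step[-1L]
      f_n <- resid_of(mu_n, lam_n)
      if (all(is.finite(f_n)) && max(abs(f_n)) < max(abs(f))) break
      h <- h / 2
      if (h < 1e-8) break
    }
    if (h < 1e-8) break
    mu <- mu_n; lambda <- lam_n; f <- f_n
  }
  if (!ok && max(abs(f)) <= tol) ok <- TRUE

  if (!ok) {
    # symmetric IPF fallback on the kernel exp(-c)
    method <- "ipf"
    K <- exp(-cmat)
    r <- sqrt(margins / rowSums(K))
    for (it in seq_len(50000L)) {
      s <- r * drop(K %*% r)  # row sums of diag(r) K diag(r)
      if (max(abs(s - margins)) <= tol) break
      r <- r * sqrt(margins / s)
    }
    pi <- outer(r, r) * K
    pi <- (pi + t(pi)) / 2
    lambda <- log(r) - mean(log(r))
    mu <- mean(log(N * pi) + cmat) # = mu + mean(lambda_i) + mean(lambda_j)
    f <- c(rowSums(pi) - margins, sum(lambda))
    ok <- max(abs(f)) <= 1e-10
    if (!ok)
      warning(sprintf(
        "design solver did not reach tolerance: residual %.3g; consider a warm start",
        max(abs(f))))
  }

  structure(list(I = I, N = N, betas = as.numeric(betas),
                 margins = as.numeric(margins),
                 mu = mu, lambda = as.numeric(lambda),
                 pi = pi_of(mu, lambda),
                 residual = max(abs(resid_of(mu, lambda))),
                 converged = ok, method = method, iterations = it),
            class = "nua_design")
}

# c(i, j) association cost under the full set of adjacent-pair betas
assoc_cost_matrix <- function(I, betas) {
  cs <- c(0, cumsum(betas))  # cs[t] = sum of betas[1..t-1]
  ij <- expand.grid(i = seq_len(I), j = seq_len(I))
  matrix((abs(ij$i - ij$j) / 2) * (cs[pmax(ij$i, ij$j)] - cs[pmin(ij$i, ij$j)]),
         I, I)
}

#' @export
print.nua_design <- function(x, digits = 4, ...) {
  cat(sprintf("Simulation design: %d x %d table, N = %g (%s solver%s)\n",
              x$I, x$I, x$N, x$method,
              if (x$converged) "" else ", NOT converged"))
  cat("  betas:", round(x$betas, digits), "\n")
  cat("  margins:", round(x$margins, digits), "\n")
  cat(sprintf("  mu = %.4f, residual = %.2e\n", x$mu, x$residual))
  invisible(x)
}

#' Re-target an existing design to a new sample size
#'
#' The probability surface depends only on `betas` and `margins`; `mu`
#' absorbs the sample size. This rescales `mu` without re-solving.
#'
#' @param design a converged `"nua_design"`.
#' @param N new sample size.
#' @return A `"nua_design"` with the same `pi` and updated `N` and `mu`.
#' @export
design_with_n <- function(design, N) {
  stopifnot(inherits(design, "nua_design"))
  design$mu <- design$mu + log(N / design$N)
  design$N <- as.numeric(N)
  design
}

#' Solve a sequence of designs with warm starts
#'
#' Solves one design per beta configuration, seeding each solve with the
#' previous solution. The margin-constraint system is sensitive to starting
#' values, so when walking a grid of tested odds ratios the previous
#' solution is the natural warm start.
#'
#' @param I,N,margins as in [nua_design()].
#' @param beta_configs list of beta vectors, ordered along the grid.
#' @param ... passed to [nua_design()].
#' @return List of `"nua_design"` objects, one per configuration.
#' @export
warm_start_path <- function(I, N, margins, beta_configs, ...) {
  stopifnot(is.list(beta_configs), length(beta_configs) >= 1L)
  out <- vector("list", length(beta_configs))
  init <- NULL
  for (k in seq_along(beta_configs)) {
    d <- nua_design(I, N, beta_configs[[k]], margins, init = init, ...)
    if (!d$converged)
      stop("design solver failed at configuration ", k,
           " (residual ", signif(d$residual, 3), ")")
    out[[k]] <- d
    init <- list(mu = d$mu, lambda = d$lambda)
  }
  out
}

#' Draw multinomial agreement tables from a design
#'
#' Counts are drawn from a full multinomial distribution over the `I^2`
#' cells with probabilities `pi` and total `N`.
#'
#' @param design a converged `"nua_design"`.
#' @param n number of tables to draw.
#' @return A count matrix if `n = 1`, otherwise a list of matrices.
#' @export
sample_table <- function(design, n = 1) {
  stopifnot(inherits(design, "nua_design"))
  if (!design$converged) stop("design did not converge")
  I <- design$I
  draws <- stats::rmultinom(n, size = design$N, prob = as.vector(design$pi))
  tabs <- lapply(seq_len(n), function(s) matrix(draws[, s], I, I))
  if (n == 1L) tabs[[1L]] else tabs
}

#' @rdname sample_table
#' @param object a `"nua_design"`.
#' @param nsim number of tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @export
simulate.nua_design <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tabs <- sample_table(object, n = nsim)
  if (nsim == 1L) list(tabs) else tabs
}

#' Write / read a design dump
#'
#' A plain-text dump of `mu`, `lambda`, `betas`, `margins` and the full
#' probability matrix, readable back for exact re-simulation.
#'
#' @param design a `"nua_design"`.
#' @param path file path.
#' @return `read_design` returns a `"nua_design"`.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "nua_design"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# nua_design I=%d N=%.17g method=%s", design$I, design$N, design$method),
    paste("mu,", format(design$mu, digits = 17)),
    paste("lambda,", paste(format(design$lambda, digits = 17), collapse = ",")),
    paste("betas,", paste(format(design$betas, digits = 17), collapse = ",")),
    paste("margins,", paste(format(design$margins, digits = 17), collapse = ","))
  ), con)
  utils::write.table(format(design$pi, digits = 17), con, sep = ",",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  I <- as.integer(sub(".*I=([0-9]+).*", "\\1", hdr))
  N <- as.numeric(sub(".*N=([0-9.eE+-]+) .*", "\\1", hdr))
  getvec <- function(key) {
    ln <- grep(paste0("^", key, ","), lines, value = TRUE)[1]
    as.numeric(strsplit(sub(paste0("^", key, ","), "", ln), ",")[[1]])
  }
  mu <- getvec("mu"); lambda <- getvec("lambda")
  betas <- getvec("betas"); margins <- getvec("margins")
  nua_design(I, N, betas, margins, init = list(mu = mu, lambda = lambda))
}
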