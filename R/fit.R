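# Newton-Raphson core on the Poisson log-likelihood. The multinomial ML fit
# of cell probabilities with fixed total is equivalent to the Poisson
# log-linear fit as long as the intercept is in the model, so the Poisson
# kernel is maximised directly.
fit_poisson_core <- function(y, X, tol = 1e-10, maxit = 100L) {
  n <- length(y)
  # start from a least-squares fit of log counts (0.5 floor keeps zeros finite)
  theta <- qr.coef(qr(X), log(pmax(y, 0.5)))
  theta[!is.finite(theta)] <- 0
  eta <- drop(X %*% theta)
  mu <- exp(eta)
  ll <- sum(y * eta - mu)
  # score tolerance scales with the table total: the score components are
  # differences of observed and fitted margins
  tol_abs <- tol * max(1, sum(y))
  converged <- FALSE
  it <- 0L
  msg <- NULL
  while (it < maxit) {
    it <- it + 1L
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) <= tol_abs) { converged <- TRUE; break }
    H <- crossprod(X * mu, X)
    step <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      msg <- "singular information matrix"
      break
    }
    # step-halving on likelihood decrease
    h <- 1
    repeat {
      theta_new <- theta + h * step
      eta_new <- drop(X %*% theta_new)
      mu_new <- exp(eta_new)
      ll_new <- sum(y * eta_new - mu_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12 * abs(ll)) break
      h <- h / 2
      if (h < 1e-10) break
    }
    if (h < 1e-10) { msg <- "step-halving failed to improve the likelihood"; break }
    theta <- theta_new; eta <- eta_new; mu <- mu_new; ll <- ll_new
  }
  if (!converged) {
    score <- drop(crossprod(X, y - mu))
    converged <- max(abs(score)) <= tol_abs
    if (!converged && is.null(msg)) msg <- "iteration cap reached"
  }
  list(theta = theta, mu = mu, loglik = ll, iterations = it,
       converged = converged, message = msg,
       max_score = max(abs(drop(crossprod(X, y - mu)))))
}

#' Fit a log-linear association model to a square agreement table
#'
#' Fits, by maximum likelihood, the log-linear model
#' `log m[i, j] = mu + lambdaA[i] + lambdaB[j] - sum_g beta[g] * x_g(i, j)`
#' to the counts of an `I x I` cross-classification of the same objects by
#' two raters, where the association covariates `x_g` are defined by an
#' adjacent-pair partition (see [association_covariate()]). With all pairs in
#' one class this is the uniform-association (UA) model, with singleton
#' classes the full non-uniform association (NUA) model, and with no class
#' the independence model. Row and column main effects are always included,
#' so fitted margins match observed margins.
#'
#' Counts are assumed multinomial with total `N`; estimation maximises the
#' equivalent Poisson likelihood by Newton-Raphson with step-halving.
#'
#' @param counts square matrix of non-negative integer counts; rows index
#'   rater A, columns rater B.
#' @param partition an adjacent-pair partition, anything accepted by
#'   [nua_partition()] (default `"uniform"`).
#' @param tol convergence tolerance on the maximum absolute score component,
#'   relative to the table total.
#' @param maxit iteration cap.
#' @return An object of class `"nua"` with components `counts`, `partition`,
#'   `mu`, `row_effects`, `col_effects` (sum-to-zero centred), `betas`
#'   (one per equality class), `fitted` (matrix of fitted means), `loglik`
#'   (Poisson kernel), `g_squared`, `df_residual`, `converged`, `iterations`.
#'   A table with an empty observed row or column is reported as
#'   `converged = FALSE` (the corresponding main effect diverges) rather than
#'   an error, so simulation loops can apply their own failure policy.
#' @seealso [anova.nua()] for likelihood-ratio comparison of nested fits,
#'   [distinguishability()] for odds ratios and degrees of distinguishability.
#' @examples
#' tab <- matrix(c(22, 5, 1, 6, 18, 4, 2, 5, 17), 3, 3)
#' fit <- nua(tab, "uniform")
#' coef(fit)
#' anova(nua(tab, "independence"), fit)
#' @export
nua <- function(counts, partition = "uniform", tol = 1e-10, maxit = 100L) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("'counts' must be a square matrix")
  I <- nrow(counts)
  storage.mode(counts) <- "double"
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("'counts' must be non-negative integers")
  N <- sum(counts)
  if (N < 1) stop("the table must contain at least one object")
  if (!inherits(partition, "nua_partition")) partition <- nua_partition(I, partition)
  if (partition$I != I) stop("partition is for ", partition$I,
                             " categories but the table has ", I)

  X <- nua_design_matrix(partition)
  y <- as.vector(counts)
  ngrp <- length(partition$groups)

  degenerate <- any(rowSums(counts) == 0) || any(colSums(counts) == 0)
  if (degenerate) {
    core <- list(theta = rep(NA_real_, ncol(X)),
                 mu = rep(NA_real_, length(y)), loglik = NA_real_,
                 iterations = 0L, converged = FALSE,
                 message = "empty observed row or column: main effect diverges",
                 max_score = NA_real_)
  } else {
    core <- fit_poisson_core(y, X, tol = tol, maxit = maxit)
  }

  theta <- core$theta
  # corner-constrained effects, re-centred to sum to zero for reporting
  lamA <- c(0, theta[2:I])
  lamB <- c(0, theta[(I + 1):(2 * I - 1)])
  mu_hat <- theta[1] + mean(lamA) + mean(lamB)
  betas <- if (ngrp) theta[(2 * I):(2 * I - 1 + ngrp)] else numeric(0)
  names(betas) <- partition$labels
  m <- matrix(core$mu, I, I, dimnames = dimnames(counts))
  g2 <- if (core$converged)
    2 * sum(ifelse(y > 0, y * log(y / core$mu), 0)) else NA_real_

  structure(list(
    counts = counts, N = N, partition = partition,
    mu = unname(mu_hat),
    row_effects = unname(lamA - mean(lamA)),
    col_effects = unname(lamB - mean(lamB)),
    betas = betas,
    coefficients = theta,
    fitted = m,
    loglik = sum(ifelse(y > 0, y * log(core$mu), 0)) - N - sum(lgamma(y + 1)),
    g_squared = g2,
    df_residual = I * I - (2L * I - 1L) - ngrp,
    n_parameters = 2L * I - 1L + ngrp,
    converged = core$converged,
    iterations = core$iterations,
    message = core$message,
    max_score = core$max_score
  ), class = "nua")
}

#' @export
print.nua <- function(x, digits = 4, ...) {
  kind <- if (length(x$partition$groups) == 0L) "independence"
    else if (length(x$partition$groups) == 1L) "uniform association (UA)"
    else "non-uniform association (NUA)"
  cat(sprintf("Log-linear %s model, %d x %d table, N = %d\n",
              kind, x$partition$I, x$partition$I, as.integer(x$N)))
  if (!x$converged) {
    cat("NOT CONVERGED:", x$message %||% "iteration cap", "\n")
    return(invisible(x))
  }
  if (length(x$betas)) {
    cat("Association parameters (log odds ratios):\n")
    print(round(x$betas, digits))
  }
  cat(sprintf("G-squared = %.*f on %d residual df\n",
              digits, x$g_squared, x$df_residual))
  invisible(x)
}

#' @export
summary.nua <- function(object, digits = 4, ...) {
  print(object, digits = digits)
  if (object$converged) {
    cat("\nRow effects (sum-to-zero):", round(object$row_effects, digits), "\n")
    cat("Column effects (sum-to-zero):", round(object$col_effects, digits), "\n")
    if (length(object$betas)) {
      cat("\nAdjacent-pair odds ratios and distinguishabilities:\n")
      dd <- distinguishability(object)
      adj <- data.frame(pair = paste(seq_len(object$partition$I - 1),
                                     2:object$partition$I, sep = "-"),
                        tau = diag(dd$tau[-nrow(dd$tau), -1, drop = FALSE]),
                        dd = diag(dd$dd[-nrow(dd$dd), -1, drop = FALSE]))
      print(adj, digits = digits, row.names = FALSE)
    }
  }
  invisible(object)
}

#' @export
coef.nua <- function(object, ...) {
  c(mu = object$mu,
    stats::setNames(object$row_effects, paste0("rowA", seq_along(object$row_effects))),
    stats::setNames(object$col_effects, paste0("colB", seq_along(object$col_effects))),
    object$betas)
}

#' @export
fitted.nua <- function(object, ...) object$fitted

#' @export
logLik.nua <- function(object, ...) {
  structure(object$loglik, df = object$n_parameters,
            nobs = object$N, class = "logLik")
}

#' @export
deviance.nua <- function(object, ...) object$g_squared

#' @export
df.residual.nua <- function(object, ...) object$df_residual

#' @export
residuals.nua <- function(object, type = c("deviance", "pearson"), ...) {
  type <- match.arg(type)
  y <- object$counts; m <- object$fitted
  if (type == "pearson") return((y - m) / sqrt(m))
  sign(y - m) * sqrt(2 * (ifelse(y > 0, y * log(y / m), 0) - (y - m)))
}

#' Simulate agreement tables from a fitted model
#'
#' Draws multinomial tables with the fitted cell probabilities
#' `m[i, j] / N` and the observed total.
#'
#' @param object a converged `"nua"` fit.
#' @param nsim number of tables.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` count matrices.
#' @export
simulate.nua <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  I <- object$partition$I
  p <- as.vector(object$fitted) / object$N
  draws <- stats::rmultinom(nsim, size = object$N, prob = p)
  lapply(seq_len(nsim), function(s) matrix(draws[, s], I, I))
}

#' Likelihood-ratio comparison of nested association models
#'
#' Compares two (or more) fits of the same table by the difference of their
#' G-squared deviances, referred to a chi-squared distribution with degrees
#' of freedom equal to the difference in the number of association equality
#' classes. Models must be nested: every equality class of the richer model
#' contained in a class of the poorer one (independence nested in all).
#'
#' @param object a fitted `"nua"` model (the null / more constrained model
#'   first is conventional, but fits are sorted by residual df).
#' @param ... further `"nua"` fits of the same table.
#' @return A data frame of class `c("anova.nua", "data.frame")` with one row
#'   per model and columns `df_residual`, `g_squared`, `delta_df`,
#'   `delta_g2`, `p_value`.
#' @examples
#' tab <- matrix(c(20, 6, 1, 5, 19, 6, 2, 4, 18), 3, 3)
#' anova(nua(tab, "uniform"), nua(tab, "full"))
#' @export
anova.nua <- function(object, ...) {
  fits <- c(list(object), list(...))
  if (length(fits) < 2L) stop("supply at least two fitted models to compare")
  if (!all(vapply(fits, inherits, logical(1), "nua")))
    stop("all arguments must be 'nua' fits")
  for (f in fits[-1]) {
    if (!identical(dim(f$counts), dim(fits[[1]]$counts)) ||
        any(f$counts != fits[[1]]$counts))
      stop("all models must be fitted to the same table")
  }
  if (any(!vapply(fits, `[[`, logical(1), "converged")))
    stop("all models must have converged")
  ord <- order(vapply(fits, `[[`, integer(1), "df_residual"), decreasing = TRUE)
  fits <- fits[ord]
  for (k in seq_along(fits)[-1]) {
    if (!is_nested(fits[[k - 1]]$partition, fits[[k]]$partition))
      stop("models are not nested")
  }
  g2 <- vapply(fits, `[[`, numeric(1), "g_squared")
  df <- vapply(fits, `[[`, integer(1), "df_residual")
  dg <- c(NA, pmax(-diff(g2), 0))
  ddf <- c(NA, -diff(df))
  p <- ifelse(is.na(dg), NA,
              ifelse(ddf == 0, 1, stats::pchisq(dg, ddf, lower.tail = FALSE)))
  out <- data.frame(
    model = vapply(fits, function(f) {
      if (length(f$partition$groups) == 0L) "independence"
      else paste(f$partition$labels, collapse = " | ")
    }, character(1)),
    df_residual = df, g_squared = g2, delta_df = ddf, delta_g2 = dg,
    p_value = p, stringsAsFactors = FALSE)
  class(out) <- c("anova.nua", "data.frame")
  out
}

#' @export
print.anova.nua <- function(x, digits = 4, ...) {
  cat("Likelihood-ratio tests of nested association models\n")
  y <- x
  for (col in c("g_squared", "delta_g2")) y[[col]] <- round(y[[col]], digits)
  y$p_value <- format.pval(y$p_value, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Likelihood-ratio test between a null and an alternative fit
#'
#' Convenience wrapper around the two-model comparison returning the test
#' components directly.
#'
#' @param fit_null,fit_alt converged `"nua"` fits of the same table, with the
#'   null partition nested in the alternative.
#' @return A list with `delta_g2`, `delta_df` and `p_value`.
#' @export
lr_test <- function(fit_null, fit_alt) {
  a <- anova.nua(fit_null, fit_alt)
  list(delta_g2 = a$delta_g2[2], delta_df = a$delta_df[2],
       p_value = a$p_value[2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
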