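#' Pairwise odds ratio implied by adjacent-pair association parameters
#'
#' Under the association coding used here the odds ratio between categories
#' `i` and `j`, `tau[i, j] = m[i,i] m[j,j] / (m[i,j] m[j,i])`, equals
#' `exp(|i - j| * (beta[min] + ... + beta[max - 1]))`: the farther apart two
#' categories are, and the larger the adjacent-pair parameters between them,
#' the easier they are to tell apart. For adjacent categories this is
#' `exp(beta[k])`; with all parameters equal (UA) it is
#' `exp(beta * (i - j)^2)`.
#'
#' @param i,j category indices.
#' @param betas numeric vector of length `I - 1`, the adjacent-pair
#'   log-odds-ratio parameters.
#' @return The odds ratio, a positive number; 1 when `i == j`.
#' @examples
#' tau_from_betas(1, 2, rep(log(3), 4))  # 3
#' tau_from_betas(1, 3, rep(log(3), 4))  # 3^4 = 81
#' @export
tau_from_betas <- function(i, j, betas) {
  I <- length(betas) + 1L
  i <- as.integer(i); j <- as.integer(j)
  if (any(c(i, j) < 1L) || any(c(i, j) > I))
    stop("category index out of range 1..", I)
  if (any(!is.finite(betas))) stop("'betas' must be finite")
  if (i == j) return(1)
  lo <- min(i, j); hi <- max(i, j)
  exp(abs(i - j) * sum(betas[lo:(hi - 1L)]))
}

#' Degree of distinguishability from an odds ratio
#'
#' The Darroch-McCloud degree of distinguishability (DD) between two
#' categories is `1 - 1/tau`: 0 when the ratings are independent (the
#' categories cannot be told apart), approaching 1 as the odds ratio grows
#' (near-perfect distinguishability), and negative for odds ratios below 1.
#'
#' @param tau positive odds ratio(s).
#' @return `1 - 1/tau`, vectorised.
#' @examples
#' dd_from_tau(c(1, 2, 3, 10, 16))  # 0, .50, .67, .90, .94
#' @export
dd_from_tau <- function(tau) {
  if (any(!is.finite(tau)) || any(tau <= 0)) stop("'tau' must be positive")
  1 - 1 / tau
}

#' Empirical odds ratio from a table of means or counts
#'
#' Computes `m[i,i] m[j,j] / (m[i,j] m[j,i])` from any positive grid of
#' fitted means (or raw counts, for diagnostics). On the fitted means of an
#' association model this reproduces [tau_from_betas()] of the fitted
#' coefficients.
#'
#' @param means square matrix of positive values.
#' @param i,j category indices.
#' @return The odds ratio. A zero among the four referenced cells is an
#'   error (no continuity correction is applied).
#' @examples
#' empirical_tau(matrix(c(9, 3, 3, 9), 2, 2), 1, 2)  # 9
#' @export
empirical_tau <- function(means, i, j) {
  means <- as.matrix(means)
  I <- nrow(means)
  if (ncol(means) != I) stop("'means' must be square")
  if (any(c(i, j) < 1L) || any(c(i, j) > I))
    stop("category index out of range 1..", I)
  cells <- c(means[i, i], means[j, j], means[i, j], means[j, i])
  if (any(cells <= 0))
    stop("odds ratio undefined: zero cell among (", i, ",", i, "), (",
         j, ",", j, "), (", i, ",", j, "), (", j, ",", i, ")")
  (means[i, i] * means[j, j]) / (means[i, j] * means[j, i])
}

#' Odds ratios and degrees of distinguishability of a fitted model
#'
#' Expands the fitted association parameters of a converged [nua()] fit into
#' the full matrix of pairwise odds ratios `tau[i, j]` and Darroch-McCloud
#' degrees of distinguishability `dd[i, j] = 1 - 1/tau[i, j]`. Values are
#' model-based (computed from the fitted betas, not from raw counts), so they
#' are defined even when the observed table contains zeros.
#'
#' @param fit a converged `"nua"` fit with an association term.
#' @return An object of class `"nua_dd"`: list with `I`, symmetric matrices
#'   `tau` (unit diagonal) and `dd` (zero diagonal), and the fitted `betas`
#'   expanded to one value per adjacent pair.
#' @examples
#' tab <- matrix(c(22, 5, 1, 6, 18, 4, 2, 5, 17), 3, 3)
#' distinguishability(nua(tab, "uniform"))
#' @export
distinguishability <- function(fit) {
  stopifnot(inherits(fit, "nua"))
  if (!fit$converged) stop("fit did not converge")
  I <- fit$partition$I
  betas <- expand_betas(fit$partition, fit$betas)
  tau <- matrix(1, I, I)
  for (i in seq_len(I)) for (j in seq_len(I))
    tau[i, j] <- tau_from_betas(i, j, betas)
  structure(list(I = I, tau = tau, dd = dd_from_tau(tau) , betas = betas),
            class = "nua_dd")
}

# expand per-class coefficients to one beta per adjacent pair; the
# independence model expands to all-zero betas (tau = 1 everywhere)
expand_betas <- function(partition, class_betas) {
  betas <- numeric(partition$I - 1L)
  for (g in seq_along(partition$groups))
    betas[partition$groups[[g]]] <- class_betas[g]
  betas
}

#' @export
print.nua_dd <- function(x, digits = 3, ...) {
  cat("Degrees of distinguishability (lower triangle), odds ratios (upper)\n")
  m <- x$dd
  m[upper.tri(m)] <- x$tau[upper.tri(x$tau)]
  print(round(m, digits))
  if (any(x$tau < 1))
    cat("note: odds ratios below 1 (negative association) present\n")
  invisible(x)
}

#' Long-format distinguishability report
#'
#' @param dd a `"nua_dd"` object.
#' @param path optional CSV path; when given the data frame is also written.
#' @return Data frame with columns `i`, `j`, `tau`, `dd` for `i < j`.
#' @export
dd_report <- function(dd, path = NULL) {
  stopifnot(inherits(dd, "nua_dd"))
  idx <- which(upper.tri(dd$tau), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1], j = idx[, 2],
                    tau = dd$tau[idx], dd = dd$dd[idx])
  out <- out[order(out$i, out$j), ]
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
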