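#' Association covariate for a group of adjacent pairs
#'
#' The association surface of the model is built from one covariate per
#' equality class of adjacent pairs. For a cell (i, j) and a class `group`
#' of pair indices, the covariate is
#' `x(i, j) = (|i - j| / 2) * #\{k in group : min(i,j) <= k <= max(i,j) - 1\}`,
#' i.e. distance times the number of the class's pair boundaries crossed
#' between the two ratings, halved. It enters the linear predictor as
#' `-beta * x(i, j)`, so larger `beta` penalises disagreement across the
#' class's boundaries. The coding makes the pairwise odds ratio
#' `tau[i, j] = exp(|i - j| * sum of the betas of the crossed pairs)`; with a
#' single class (UA) this is `exp(beta * (i - j)^2)` and the adjacent-pair
#' odds ratio is `exp(beta)`.
#'
#' @param i,j category indices in `1..I`.
#' @param group integer vector of adjacent-pair indices (subset of `1..I-1`).
#' @param I number of categories (used only for index validation).
#' @return The covariate value, a non-negative number; 0 on the diagonal.
#' @examples
#' association_covariate(1, 5, 1:4, I = 5)  # (5-1)^2 / 2 = 8 under UA
#' association_covariate(2, 4, 1, I = 5)    # pair 1 not crossed: 0
#' @export
association_covariate <- function(i, j, group, I) {
  i <- as.integer(i); j <- as.integer(j)
  if (any(c(i, j) < 1L) || any(c(i, j) > I))
    stop("category index out of range 1..", I)
  if (length(group) && (any(group < 1L) || any(group > I - 1L)))
    stop("pair index out of range 1..", I - 1L)
  lo <- min(i, j); hi <- max(i, j)
  (abs(i - j) / 2) * sum(group >= lo & group <= hi - 1L)
}

#' Design matrix of a log-linear association model
#'
#' Rows are the `I^2` cells of the square table in column-major order
#' (`as.vector` of the count matrix); columns are the intercept, `I - 1` row
#' main effects, `I - 1` column main effects (corner constraint: category 1
#' is the reference for both raters) and minus-the-covariate of each
#' adjacent-pair equality class, so fitted coefficients on the association
#' columns are the `beta` log-odds-ratio parameters directly.
#'
#' @param partition a [nua_partition()].
#' @return Numeric matrix with `I^2` rows, of full column rank, with a
#'   `"cells"` attribute giving the (i, j) index of each row.
#' @export
nua_design_matrix <- function(partition) {
  stopifnot(inherits(partition, "nua_partition"))
  I <- partition$I
  cells <- expand.grid(i = seq_len(I), j = seq_len(I))
  p <- 1L + 2L * (I - 1L) + length(partition$groups)
  X <- matrix(0, nrow = I * I, ncol = p)
  colnames(X) <- c("(Intercept)",
                   paste0("rowA", 2:I), paste0("colB", 2:I),
                   partition$labels)
  X[, 1L] <- 1
  for (r in 2:I) {
    X[cells$i == r, r] <- 1
    X[cells$j == r, I - 1L + r] <- 1
  }
  for (g in seq_along(partition$groups)) {
    X[, 2L * I - 1L + g] <- -mapply(association_covariate,
                                    cells$i, cells$j,
                                    MoreArgs = list(group = partition$groups[[g]],
                                                    I = I))
  }
  attr(X, "cells") <- cells
  X
}
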