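#' Read and write square agreement tables as CSV
#'
#' The format is `I` data rows of `I` comma-separated non-negative integers,
#' with an optional single header row of category labels. Round-trips
#' exactly.
#'
#' @param path file path.
#' @param counts square integer matrix.
#' @param labels optional character vector of category labels written as the
#'   header row.
#' @return `read_square_table` returns an integer matrix (with dimnames when
#'   a header is present).
#' @export
read_square_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty table file: ", path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(trimws(first)))))
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        header = has_header, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("table in ", path, " is ", nrow(m), " x ", ncol(m), ", not square")
  storage.mode(m) <- "double"
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("table in ", path, " must contain non-negative integers")
  if (has_header) rownames(m) <- colnames(m)
  m
}

#' @rdname read_square_table
#' @export
write_square_table <- function(counts, path, labels = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts))
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(counts))
    colnames(counts) <- labels
  }
  utils::write.table(counts, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = !is.null(labels))
  invisible(path)
}

#' Plain-text fit report
#'
#' Writes the parameter estimates, fitted means, deviance and residual
#' degrees of freedom of a fit to a small CSV-style report.
#'
#' @param fit a `"nua"` fit.
#' @param path output file.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "nua"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# nua fit: I=%d N=%d converged=%s",
                     fit$partition$I, as.integer(fit$N), fit$converged), con)
  cf <- coef(fit)
  writeLines("parameter,estimate", con)
  writeLines(sprintf("%s,%.17g", names(cf), cf), con)
  writeLines(sprintf("# G2,%.17g", fit$g_squared), con)
  writeLines(sprintf("# df_residual,%d", fit$df_residual), con)
  writeLines("# fitted means (row-major lines):", con)
  utils::write.table(format(fit$fitted, digits = 17), con, sep = ",",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
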