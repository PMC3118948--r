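#' Presentation rounding, half away from zero
#'
#' Power tables are stored and interpolated at full precision and rounded
#' only for display. Display rounding is half-away-from-zero (so 0.335
#' renders as 0.34), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 2, the tabulation convention).
#' @return Rounded values.
#' @examples
#' round_display(c(0.335, 0.725, 0.905))  # 0.34 0.73 0.91
#' @export
round_display <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Interpolate tabulated power at an intermediate association parameter
#'
#' Power tables are computed on a grid of association parameters
#' `beta = log(K)`; power at an intermediate `beta` is obtained by linear
#' interpolation between the two bracketing grid rows, column by column,
#' using the stored full-precision values (display rounding plays no part).
#'
#' @param table a `"nua_power_table"` (from [nua_power_grid()] or
#'   [read_power_table()]).
#' @param beta association parameter at which to interpolate; must lie
#'   within the table's beta range.
#' @return Named numeric vector of interpolated powers, one per sample size.
#' @examples
#' tab <- read_power_table(system.file("extdata", "table3_panel_b.csv",
#'                                     package = "nuapower"))
#' interp_power_at_beta(tab, 2.25)
#' @export
interp_power_at_beta <- function(table, beta) {
  stopifnot(inherits(table, "nua_power_table"), length(beta) == 1L,
            is.finite(beta))
  b <- table$betas
  if (is.unsorted(b)) stop("table beta grid must be increasing")
  if (beta < b[1] || beta > b[length(b)])
    stop(sprintf("beta = %g outside the table range [%g, %g]",
                 beta, b[1], b[length(b)]))
  hi <- which(b >= beta)[1]
  if (b[hi] == beta) {
    out <- table$power[hi, ]
  } else {
    lo <- hi - 1L
    w <- (beta - b[lo]) / (b[hi] - b[lo])
    out <- (1 - w) * table$power[lo, ] + w * table$power[hi, ]
  }
  stats::setNames(as.numeric(out), paste0("N", table$ns))
}

#' Required sample size for a target power
#'
#' Interpolates the table at `beta` (see [interp_power_at_beta()]), finds
#' the two sample sizes whose interpolated powers bracket `target`, and
#' inverts the linear interpolation in N. All arithmetic uses full-precision
#' interpolated powers, not display-rounded values. No extrapolation is
#' performed: a target outside the attainable range on the N grid is an
#' error.
#'
#' @param table a `"nua_power_table"`.
#' @param beta association parameter of interest.
#' @param target target power, in (0, 1).
#' @return List with `n_real` (interpolated, fractional) and `n_integer`
#'   (`ceiling(n_real)`, the smallest usable sample size).
#' @examples
#' tab <- read_power_table(system.file("extdata", "table3_panel_b.csv",
#'                                     package = "nuapower"))
#' required_n(tab, beta = 2.25, target = 0.80)  # 182.61 -> 183
#' @export
required_n <- function(table, beta, target) {
  stopifnot(length(target) == 1L, is.finite(target), target > 0, target < 1)
  p <- interp_power_at_beta(table, beta)
  ns <- table$ns
  if (target <= p[1]) {
    if (target == p[1]) return(list(n_real = ns[1], n_integer = as.integer(ns[1])))
    stop(sprintf("target power %.3g already attained at the smallest N (%g)",
                 target, ns[1]))
  }
  if (target > max(p))
    stop(sprintf("target power %.3g unattainable on the N grid (max %.4g)",
                 target, max(p)))
  hi <- which(p >= target)[1]
  lo <- hi - 1L
  n_real <- ns[lo] + (ns[hi] - ns[lo]) * (target - p[lo]) / (p[hi] - p[lo])
  list(n_real = unname(n_real), n_integer = as.integer(ceiling(n_real - 1e-9)))
}

#' Read and write power tables as CSV
#'
#' The dialect has `#`-prefixed metadata comment lines (hypothesis, null
#' odds ratio, margins, alpha, nsim, seed) followed by a header row
#' `beta,OR,DD,N<n1>,...` and one data row per tested odds ratio. Values are
#' written at full precision; 2-decimal rounding is presentation-only. A
#' missing DD column is recomputed as `1 - 1/OR` on read.
#'
#' @param table a `"nua_power_table"`.
#' @param path file path.
#' @return `read_power_table` returns a `"nua_power_table"`;
#'   `write_power_table` returns `path` invisibly.
#' @export
write_power_table <- function(table, path) {
  stopifnot(inherits(table, "nua_power_table"))
  meta <- c(
    sprintf("# hypothesis: %s", table$hypothesis %||% "NA"),
    sprintf("# null_or: %s", format(table$null_or %||% NA)),
    sprintf("# margins: %s", paste(format(table$margins, digits = 17), collapse = " ")),
    sprintf("# alpha: %s", format(table$alpha %||% NA)),
    sprintf("# nsim: %s", format(table$nsim %||% NA)),
    sprintf("# seed: %s", format(table$seed %||% NA)))
  df <- data.frame(beta = table$betas, OR = table$or, DD = table$dd,
                   table$power, check.names = FALSE)
  colnames(df)[-(1:3)] <- paste0("N", format(table$ns, trim = TRUE,
                                             scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_power_table
#' @export
read_power_table <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  getmeta <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (!length(ln)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  hdr <- names(df)
  if (!all(c("beta", "OR") %in% hdr))
    stop("malformed power-table header in ", path,
         ": need at least 'beta' and 'OR' columns")
  ncols <- grep("^N[0-9]+$", hdr, value = TRUE)
  if (!length(ncols)) stop("no sample-size (N...) columns in ", path)
  ns <- as.numeric(sub("^N", "", ncols))
  if (is.unsorted(ns, strictly = TRUE))
    stop("sample-size columns must be strictly increasing in ", path)
  dd <- if ("DD" %in% hdr) df$DD else 1 - 1 / df$OR
  margins <- getmeta("margins")
  structure(list(
    hypothesis = getmeta("hypothesis"),
    null_or = as.numeric(getmeta("null_or") %||% NA),
    margins = if (!is.null(margins)) as.numeric(strsplit(margins, "\\s+")[[1]]),
    I = NA_integer_,
    alpha = as.numeric(getmeta("alpha") %||% NA),
    nsim = as.numeric(getmeta("nsim") %||% NA),
    seed = as.numeric(getmeta("seed") %||% NA),
    or = df$OR, betas = df$beta, dd = dd, ns = ns,
    power = as.matrix(df[, ncols, drop = FALSE]),
    se = NULL, failed = NULL), class = "nua_power_table")
}
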