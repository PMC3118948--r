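#' Adjacent-pair partitions: which association parameters are constrained equal
#'
#' On an ordinal scale with `I` categories there are `I - 1` adjacent category
#' pairs, indexed `k = 1, ..., I - 1` (pair `k` is the pair of categories
#' `(k, k + 1)`). A log-linear association model attaches one log-odds-ratio
#' parameter `beta[k]` to each pair; a partition of the pair indices into
#' equality classes defines the model:
#'
#' * one class containing all pairs: the uniform-association (UA) model;
#' * `I - 1` singleton classes: the full non-uniform association (NUA) model;
#' * no classes at all: the independence model (no association term).
#'
#' @param I integer number of scale categories (`I >= 2`; `I >= 3` for any
#'   partition with more than one class).
#' @param groups either a list of integer vectors partitioning
#'   `1:(I - 1)`, or one of the shortcut strings `"uniform"`, `"full"`,
#'   `"independence"`, or a compact specification string (see
#'   [parse_partition()]).
#' @return An object of class `"nua_partition"`: a list with elements `I`,
#'   `groups` (list of sorted integer vectors) and `labels`.
#' @examples
#' nua_partition(5, "uniform")
#' nua_partition(5, list(1, 2:4))        # beta[1,2] free, the rest equal
#' nua_partition(5, "12|2345")           # same, as a compact string
#' nua_partition(5, list(c(1, 4), 2:3))  # symmetric-extremes grouping
#' @export
nua_partition <- function(I, groups = "uniform") {
  I <- as.integer(I)
  if (length(I) != 1L || is.na(I) || I < 2L)
    stop("'I' must be a single integer >= 2")
  npair <- I - 1L
  if (is.character(groups)) {
    stopifnot(length(groups) == 1L)
    groups <- switch(groups,
      uniform      = list(seq_len(npair)),
      full         = as.list(seq_len(npair)),
      independence = list(),
      parse_partition(groups, I)$groups
    )
  }
  if (!is.list(groups)) stop("'groups' must be a list, or a specification string")
  groups <- lapply(groups, function(g) sort(unique(as.integer(g))))
  ks <- unlist(groups)
  if (length(groups)) {
    if (any(!is.finite(ks)) || any(ks < 1L) || any(ks > npair))
      stop("pair indices must lie in 1..", npair)
    if (anyDuplicated(ks) || length(ks) != npair)
      stop("'groups' must partition the adjacent-pair indices 1..", npair,
           " into disjoint classes")
    if (length(groups) > 1L && I < 3L)
      stop("non-uniform association needs I >= 3")
  }
  labels <- vapply(groups, function(g)
    paste(sprintf("b%d%d", g, g + 1L), collapse = "="), character(1))
  structure(list(I = I, groups = groups, labels = labels),
            class = "nua_partition")
}

#' Parse a compact partition specification string
#'
#' Equality classes are separated by `"|"`; within a class, members are
#' separated by `","`. Each member is either a single adjacent-pair index
#' (`"1"` = pair of categories 1 and 2) or a run of consecutive category
#' digits (`"2345"` = pairs (2,3), (3,4), (4,5)). The strings `"uniform"`,
#' `"full"` and `"independence"` are also accepted.
#'
#' @param spec specification string, e.g. `"12|2345"` (pair (1,2) free, the
#'   other three equal) or `"12,45|23,34"` (symmetric extremes vs middle).
#' @param I number of categories.
#' @return A `"nua_partition"` object.
#' @examples
#' parse_partition("12|2345", 5)
#' parse_partition("12,45|23,34", 5)
#' @export
parse_partition <- function(spec, I) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- trimws(spec)
  if (spec %in% c("uniform", "full", "independence"))
    return(nua_partition(I, spec))
  toks <- strsplit(spec, "|", fixed = TRUE)[[1]]
  groups <- lapply(toks, function(tok) {
    members <- strsplit(trimws(tok), ",", fixed = TRUE)[[1]]
    unlist(lapply(trimws(members), function(m) {
      if (!grepl("^[0-9]+$", m))
        stop("cannot parse partition member '", m, "' in '", spec, "'")
      d <- as.integer(strsplit(m, "")[[1]])
      if (length(d) == 1L) return(d)
      if (any(diff(d) != 1L))
        stop("category run '", m, "' is not consecutive in '", spec, "'")
      d[-length(d)]
    }))
  })
  nua_partition(I, groups)
}

#' @export
print.nua_partition <- function(x, ...) {
  kind <- if (length(x$groups) == 0L) "independence"
    else if (length(x$groups) == 1L) "uniform association (UA)"
    else if (length(x$groups) == x$I - 1L) "full non-uniform association (NUA)"
    else "grouped non-uniform association (NUA)"
  cat(sprintf("Adjacent-pair partition on %d categories: %s\n", x$I, kind))
  if (length(x$groups))
    cat("  classes:", paste(x$labels, collapse = " | "), "\n")
  invisible(x)
}

#' Test whether one partition is nested in another
#'
#' The null model is nested in the alternative when every equality class of
#' the alternative is contained in a class of the null (the alternative
#' refines the null; independence is nested in every association model).
#'
#' @param null,alt `"nua_partition"` objects on the same number of categories.
#' @return `TRUE` or `FALSE`.
#' @export
is_nested <- function(null, alt) {
  stopifnot(inherits(null, "nua_partition"), inherits(alt, "nua_partition"))
  if (null$I != alt$I) return(FALSE)
  if (length(null$groups) == 0L) return(TRUE)
  if (length(alt$groups) == 0L) return(FALSE)
  all(vapply(alt$groups, function(g) {
    any(vapply(null$groups, function(h) all(g %in% h), logical(1)))
  }, logical(1)))
}
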