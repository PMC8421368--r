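#' Counts-per-million normalisation
#'
#' Scales each sample (column) of a count matrix to counts per million:
#' \code{CPM = count / sum(count) * 1e6}, per sample. No gene filtering is
#' applied by default; an optional minimum-total-count filter can drop
#' genes whose summed raw count across samples falls below a threshold.
#'
#' @param counts a [CountMatrix-class].
#' @param min_total optional minimum total raw count per gene; genes below
#'   it are dropped before scaling. Default 0 (keep everything).
#' @return numeric matrix of CPM values, same dimnames as the (possibly
#'   filtered) input; every column sums to 1e6.
#' @examples
#' m <- countMatrix(matrix(c(90L, 10L), 2,
#'                  dimnames = list(c("g1", "g2"), "s1")))
#' cpmNormalize(m)  # 900000, 100000
#' @export
cpmNormalize <- function(counts, min_total = 0) {
  stopifnot(is(counts, "CountMatrix"))
  a <- assayValues(counts)
  if (min_total > 0) {
    keep <- rowSums(a) >= min_total
    if (!any(keep)) stop("min_total filter removed every gene",
                         call. = FALSE)
    a <- a[keep, , drop = FALSE]
  }
  tot <- colSums(a)
  zero <- which(tot == 0)
  if (length(zero))
    stop("all-zero sample column(s): ",
         paste(colnames(a)[zero], collapse = ", "), call. = FALSE)
  sweep(a, 2L, tot, "/") * 1e6
}

#' Log2 transform with pseudocount
#'
#' Element-wise \code{log2(cpm + 1)}; the +1 pseudocount is added on the
#' CPM scale, so zero counts map to exactly 0. Returns a tagged
#' [LogExpressionMatrix-class] so downstream steps can assert they are
#' working in log2(CPM+1) space.
#'
#' @param cpm numeric matrix of non-negative CPM values with gene
#'   rownames and sample colnames.
#' @return a [LogExpressionMatrix-class].
#' @examples
#' cpm <- matrix(c(0, 1, 999999), 3,
#'               dimnames = list(c("a", "b", "c"), "s1"))
#' assayValues(log2Pseudocount(cpm))
#' @export
log2Pseudocount <- function(cpm) {
  if (!is.matrix(cpm)) stop("cpm must be a matrix", call. = FALSE)
  if (anyNA(cpm) || any(cpm < 0))
    stop("CPM values must be non-negative and non-missing", call. = FALSE)
  new("LogExpressionMatrix", assay = log2(cpm + 1), spaceTag = "log2cpm")
}

#' Normalise raw counts to log2(CPM+1)
#'
#' Convenience composition of [cpmNormalize()] and [log2Pseudocount()].
#'
#' @inheritParams cpmNormalize
#' @return a [LogExpressionMatrix-class].
#' @export
normalizeCounts <- function(counts, min_total = 0) {
  log2Pseudocount(cpmNormalize(counts, min_total = min_total))
}
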