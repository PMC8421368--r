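## Consensus gene-list compilation across single-sample comparisons.
##
## Two rule engines: the hydrogel-culture list (overexpressed in all
## three test-vs-control comparisons, with the overexpression reaching
## the prediction-interval call in at least two), and the stem-cell list
## (overexpressed in at least two of three comparisons of one study, or
## in one of them with support from at least one further study).

#' Per-comparison overexpression flags
#'
#' Reduces a [ComparisonResult-class] to the two booleans the consensus
#' rules consume: \code{overexpressed} (log2 difference beyond the
#' threshold in the requested direction) and \code{significant} (the full
#' prediction-interval call, which implies the former).
#'
#' @param result a [ComparisonResult-class].
#' @param direction \code{"up"} (default) or \code{"down"}; the down
#'   direction is the mirror rule (delta < -threshold, call "down").
#' @param delta_threshold log2 threshold, default 1.
#' @return data.frame with columns \code{gene}, \code{overexpressed},
#'   \code{significant}.
#' @export
comparisonFlags <- function(result, direction = c("up", "down"),
                            delta_threshold = 1) {
  stopifnot(is(result, "ComparisonResult"))
  direction <- match.arg(direction)
  g <- result@genes
  if (direction == "up") {
    over <- g$delta > delta_threshold
    sig <- g$call == "up"
  } else {
    over <- g$delta < -delta_threshold
    sig <- g$call == "down"
  }
  data.frame(gene = g$gene, overexpressed = over, significant = sig,
             stringsAsFactors = FALSE)
}

.alignFlags <- function(flags) {
  genes <- flags[[1L]]$gene
  for (f in flags) {
    if (!all(c("gene", "overexpressed") %in% names(f)))
      stop("each flag table needs 'gene' and 'overexpressed' columns",
           call. = FALSE)
    if (!identical(sort(f$gene), sort(genes)))
      stop("flag tables cover different gene sets", call. = FALSE)
  }
  lapply(flags, function(f) f[match(genes, f$gene), , drop = FALSE])
}

#' Compile the consistently-overexpressed consensus list
#'
#' A gene enters the list iff it is overexpressed in all supplied
#' comparisons and the overexpression is significant (full
#' prediction-interval call) in at least \code{min_significant} of them.
#' The default configuration — exactly three comparisons, significance in
#' at least two — is the rule used to build a culture-condition gene list
#' from three patient lines.
#'
#' @param flags list of flag tables from [comparisonFlags()], one per
#'   comparison; must have length \code{n_comparisons}.
#' @param name name of the resulting list.
#' @param n_comparisons required number of comparisons (default 3).
#' @param min_significant minimum number of significant comparisons
#'   (default 2).
#' @return list with elements \code{name}, \code{members} (character
#'   vector) and \code{provenance} (per-gene data.frame of
#'   overexpression/significance counts, members only).
#' @examples
#' f <- function(over, sig) data.frame(gene = "A", overexpressed = over,
#'                                     significant = sig)
#' compileConsensusList(list(f(TRUE, TRUE), f(TRUE, TRUE),
#'                           f(TRUE, FALSE)))$members
#' @export
compileConsensusList <- function(flags, name = "3D-GMH list",
                                 n_comparisons = 3L, min_significant = 2L) {
  if (length(flags) != n_comparisons)
    stop("expected exactly ", n_comparisons, " comparisons, got ",
         length(flags), call. = FALSE)
  flags <- .alignFlags(flags)
  genes <- flags[[1L]]$gene
  over <- Reduce(`+`, lapply(flags, function(f)
    as.integer(f$overexpressed)))
  sig <- Reduce(`+`, lapply(flags, function(f) {
    if (!"significant" %in% names(f))
      stop("flag tables need a 'significant' column", call. = FALSE)
    as.integer(f$significant & f$overexpressed)
  }))
  keep <- over == length(flags) & sig >= min_significant
  prov <- data.frame(gene = genes, n_overexpressed = over,
                     n_significant = sig,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(prov) <- NULL
  list(name = name, members = genes[keep], provenance = prov)
}

#' Compile the externally-supported consensus list
#'
#' A gene enters the list iff it is overexpressed in at least two of the
#' three primary-study comparisons, or in at least one of them while also
#' flagged by at least one supporting study. This is the rule used to
#' build a stem-cell (GSC vs DGC) gene list around one single-cell study
#' with corroboration from further cohorts.
#'
#' @param primary_flags list of exactly 3 flag tables
#'   ([comparisonFlags()], only \code{overexpressed} is used) from the
#'   primary study's comparisons.
#' @param support data.frame with a \code{gene} column plus one logical
#'   column per supporting study (>= 1 column); must cover the same
#'   genes.
#' @param name name of the resulting list.
#' @return same shape as [compileConsensusList()]; provenance records the
#'   primary overexpression count and the number of supporting studies.
#' @export
compileSupportedList <- function(primary_flags, support,
                                 name = "GSC list") {
  if (length(primary_flags) != 3L)
    stop("expected exactly 3 primary comparisons, got ",
         length(primary_flags), call. = FALSE)
  if (!"gene" %in% names(support) || ncol(support) < 2L)
    stop("support needs a 'gene' column and >= 1 study column",
         call. = FALSE)
  primary_flags <- .alignFlags(primary_flags)
  genes <- primary_flags[[1L]]$gene
  if (!identical(sort(support$gene), sort(genes)))
    stop("support table covers a different gene set", call. = FALSE)
  support <- support[match(genes, support$gene), , drop = FALSE]
  over <- Reduce(`+`, lapply(primary_flags, function(f)
    as.integer(f$overexpressed)))
  supp <- rowSums(as.matrix(support[, setdiff(names(support), "gene"),
                                    drop = FALSE]) > 0)
  keep <- over >= 2L | (over >= 1L & supp >= 1L)
  prov <- data.frame(gene = genes, n_overexpressed = over,
                     n_supporting = supp,
                     stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(prov) <- NULL
  list(name = name, members = genes[keep], provenance = prov)
}
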