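#' @import methods
#' @importFrom stats median qt quantile rbinom rexp rnbinom rnorm runif sd
#'   setNames rpois
#' @importFrom utils head
NULL

.checkMatrixIds <- function(genes, samples, what = "sample") {
  msg <- character(0)
  if (length(genes) < 1L) msg <- c(msg, "at least one gene is required")
  if (length(samples) < 1L)
    msg <- c(msg, sprintf("at least one %s is required", what))
  dg <- unique(genes[duplicated(genes)])
  if (length(dg))
    msg <- c(msg, sprintf("duplicated gene id(s): %s",
                          paste(head(dg, 5L), collapse = ", ")))
  ds <- unique(samples[duplicated(samples)])
  if (length(ds))
    msg <- c(msg, sprintf("duplicated %s id(s): %s", what,
                          paste(head(ds, 5L), collapse = ", ")))
  msg
}

#' Raw count matrix
#'
#' An S4 container for a genes-by-samples matrix of non-negative integer
#' read counts. Gene and sample identifiers are opaque case-sensitive
#' strings (symbols or ENSEMBL ids alike); no identifier mapping is ever
#' performed. Missing values are not permitted.
#'
#' @slot assay numeric matrix of counts, genes in rows, samples in columns,
#'   with complete dimnames.
#'
#' @seealso [readCounts()], [cpmNormalize()], [simulateCountPair()]
#' @export
setClass("CountMatrix", representation(assay = "matrix"))

setValidity("CountMatrix", function(object) {
  a <- object@assay
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("assay must have gene rownames and sample colnames")
  msg <- .checkMatrixIds(rownames(a), colnames(a))
  if (anyNA(a)) msg <- c(msg, "missing values are not permitted")
  else {
    if (any(a < 0)) {
      bad <- which(a < 0, arr.ind = TRUE)[1L, ]
      msg <- c(msg, sprintf("negative count at gene '%s', sample '%s'",
                            rownames(a)[bad[1L]], colnames(a)[bad[2L]]))
    }
    if (any(a != floor(a)))
      msg <- c(msg, "counts must be whole numbers")
  }
  if (length(msg)) msg else TRUE
})

#' Log-scale expression matrix
#'
#' Genes-by-samples matrix of log2(CPM + 1) values. The \code{spaceTag}
#' slot records the transformation so that downstream code can refuse to
#' double-transform or to mix spaces.
#'
#' @slot assay numeric matrix, genes in rows, units (samples/cells) in
#'   columns.
#' @slot spaceTag single string, always \code{"log2cpm"}.
#'
#' @seealso [log2Pseudocount()], [callGenes()], [ssgseaScores()]
#' @export
setClass("LogExpressionMatrix",
         representation(assay = "matrix", spaceTag = "character"))

setValidity("LogExpressionMatrix", function(object) {
  a <- object@assay
  if (is.null(rownames(a)) || is.null(colnames(a)))
    return("assay must have gene rownames and unit colnames")
  msg <- .checkMatrixIds(rownames(a), colnames(a), "unit")
  if (!identical(object@spaceTag, "log2cpm"))
    msg <- c(msg, "spaceTag must be the literal \"log2cpm\"")
  if (anyNA(a) || any(!is.finite(a)))
    msg <- c(msg, "values must be finite")
  else if (any(a < 0))
    msg <- c(msg, "log2(CPM + 1) values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Gene set and gene set collection
#'
#' \code{GeneSet} holds one named set of unique gene identifiers with an
#' optional free-text description; \code{GeneSetCollection} is an ordered
#' list of \code{GeneSet} objects with unique names, as read from a GMT
#' file. Used for glioblastoma meta-modules (MES1/MES2/AC/OPC/NPC1/NPC2,
#' G1S/G2M), hallmark-like sets, and compiled consensus lists.
#'
#' @slot name single string, the set name.
#' @slot description single string, may be empty.
#' @slot members character vector of unique gene ids, length >= 1.
#'
#' @aliases GeneSetCollection-class
#' @seealso [readGmt()], [geneSet()], [gseaPreranked()], [ssgseaScore()]
#' @export
setClass("GeneSet",
         representation(name = "character", description = "character",
                        members = "character"))

setValidity("GeneSet", function(object) {
  msg <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a single non-empty string")
  if (length(object@description) != 1L)
    msg <- c(msg, "description must be a single string")
  if (length(object@members) < 1L)
    msg <- c(msg, "members must be non-empty")
  if (anyDuplicated(object@members))
    msg <- c(msg, "members must be unique")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  if (!all(vapply(object@sets, is, logical(1L), "GeneSet")))
    return("all elements must be GeneSet objects")
  nms <- vapply(object@sets, function(s) s@name, character(1L))
  if (anyDuplicated(nms))
    return(sprintf("duplicated set name(s): %s",
                   paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  TRUE
})

#' Replicate-free differential-expression result
#'
#' The result of one single-sample test-vs-control comparison: the global
#' ordinary-least-squares fit of the test sample on the control sample over
#' all genes, and the per-gene prediction-interval calls. The per-gene
#' table carries, for every gene: the control and test log2(CPM+1) values,
#' the fitted prediction and its interval, the log2 difference
#' (test - control), the call (\code{"up"}, \code{"down"} or \code{"none"})
#' and the z-score \code{|predicted - test| / |(predicted - upperPI)/2|}.
#'
#' @slot testLabel,controlLabel sample labels of the comparison.
#' @slot piLevel prediction-interval coverage, in (0,1); default 0.99.
#' @slot fit list with the regression summaries (slope, intercept, n,
#'   xMean, sxx, residualSd, df) as returned by [fitRegression()].
#' @slot genes data.frame with columns \code{gene}, \code{control},
#'   \code{test}, \code{predicted}, \code{pi_lower}, \code{pi_upper},
#'   \code{delta}, \code{call}, \code{z_score}, \code{sd_used}.
#'
#' @seealso [callGenes()], [volcanoTable()], [rankGenes()],
#'   [comparisonFlags()]
#' @export
setClass("ComparisonResult",
         representation(testLabel = "character", controlLabel = "character",
                        piLevel = "numeric", fit = "list",
                        genes = "data.frame"))

setValidity("ComparisonResult", function(object) {
  msg <- character(0)
  if (length(object@piLevel) != 1L || object@piLevel <= 0 ||
      object@piLevel >= 1)
    msg <- c(msg, "piLevel must be a single probability in (0,1)")
  need <- c("gene", "control", "test", "predicted", "pi_lower", "pi_upper",
            "delta", "call", "z_score", "sd_used")
  if (!all(need %in% names(object@genes)))
    msg <- c(msg, "genes table is missing required columns")
  else {
    g <- object@genes
    if (anyDuplicated(g$gene)) msg <- c(msg, "duplicated genes in table")
    if (!all(g$call %in% c("up", "down", "none")))
      msg <- c(msg, "call must be one of up/down/none")
    if (any(g$pi_lower > g$predicted | g$predicted > g$pi_upper))
      msg <- c(msg, "prediction must lie inside its interval")
    if (any(g$z_score < 0, na.rm = TRUE))
      msg <- c(msg, "z scores must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Single-sample GSEA score matrix
#'
#' Scores of scoring units (bulk samples, single cells, clusters, or
#' spatial features) against a collection of gene sets; one finite score
#' per unit and set, plus the rank-weighting exponent used.
#'
#' @slot scores numeric matrix, units in rows, gene sets in columns.
#' @slot alpha single numeric, the rank-weight exponent (default 0.25).
#'
#' @seealso [ssgseaScores()], [stratifyByScoreMedians()],
#'   [assignCellModules()]
#' @export
setClass("SsgseaScores",
         representation(scores = "matrix", alpha = "numeric"))

setValidity("SsgseaScores", function(object) {
  msg <- character(0)
  if (is.null(rownames(object@scores)) || is.null(colnames(object@scores)))
    msg <- c(msg, "scores must have unit rownames and set colnames")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "scores must be finite")
  if (length(object@alpha) != 1L || object@alpha < 0)
    msg <- c(msg, "alpha must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Kaplan-Meier curve with median and confidence interval
#'
#' Product-limit estimate for one group: event times, survival estimates,
#' numbers at risk, Greenwood variance, and the median survival time with
#' its 95% confidence interval (either side may be \code{NA} when the
#' curve never crosses the corresponding level).
#'
#' @slot group single string labelling the group.
#' @slot time,survival,atRisk,events,greenwoodVar parallel numeric vectors
#'   over the observed event times (ascending).
#' @slot median,medianLower,medianUpper single numerics, \code{NA} when
#'   undefined.
#'
#' @seealso [kmFit()], [logrankTest()]
#' @export
setClass("KmCurve",
         representation(group = "character", time = "numeric",
                        survival = "numeric", atRisk = "numeric",
                        events = "numeric", greenwoodVar = "numeric",
                        median = "numeric", medianLower = "numeric",
                        medianUpper = "numeric"))

setValidity("KmCurve", function(object) {
  msg <- character(0)
  n <- length(object@time)
  if (length(object@survival) != n || length(object@atRisk) != n ||
      length(object@greenwoodVar) != n || length(object@events) != n)
    msg <- c(msg, "time, survival, atRisk, events, greenwoodVar must align")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "event times must be strictly ascending")
  if (n && (any(object@survival < 0) || any(object@survival > 1)))
    msg <- c(msg, "survival estimates must lie in [0,1]")
  if (n > 1L && any(diff(object@survival) > 1e-12))
    msg <- c(msg, "survival must be non-increasing")
  if (length(msg)) msg else TRUE
})
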