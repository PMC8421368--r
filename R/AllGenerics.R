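#' Accessors for gliomaNiche containers
#'
#' \code{geneIds} and \code{sampleIds} return the row and column
#' identifiers of a matrix-like container; \code{assayValues} the
#' underlying numeric matrix; \code{scoreMatrix} the unit-by-set score
#' matrix of an [SsgseaScores-class] object; \code{members} the gene ids
#' of a [GeneSet-class]; \code{setNamesOf} the set names of a
#' [GeneSetCollection-class].
#'
#' @param x a gliomaNiche object.
#' @return character vector of ids, or a numeric matrix.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("assayValues", function(x) standardGeneric("assayValues"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname accessors
#' @export
setGeneric("setNamesOf", function(x) standardGeneric("setNamesOf"))

#' @rdname accessors
#' @export
setMethod("geneIds", "CountMatrix", function(x) rownames(x@assay))
#' @rdname accessors
#' @export
setMethod("geneIds", "LogExpressionMatrix", function(x) rownames(x@assay))
#' @rdname accessors
#' @export
setMethod("geneIds", "ComparisonResult", function(x) x@genes$gene)
#' @rdname accessors
#' @export
setMethod("sampleIds", "CountMatrix", function(x) colnames(x@assay))
#' @rdname accessors
#' @export
setMethod("sampleIds", "LogExpressionMatrix", function(x) colnames(x@assay))
#' @rdname accessors
#' @export
setMethod("assayValues", "CountMatrix", function(x) x@assay)
#' @rdname accessors
#' @export
setMethod("assayValues", "LogExpressionMatrix", function(x) x@assay)
#' @rdname accessors
#' @export
setMethod("scoreMatrix", "SsgseaScores", function(x) x@scores)
#' @rdname accessors
#' @export
setMethod("members", "GeneSet", function(x) x@members)
#' @rdname accessors
#' @export
setMethod("setNamesOf", "GeneSetCollection",
          function(x) vapply(x@sets, function(s) s@name, character(1L)))

#' @describeIn accessors number of sets in a collection.
#' @export
setMethod("length", "GeneSetCollection", function(x) length(x@sets))

#' @describeIn accessors extract one [GeneSet-class] by position or name.
#' @param i index or set name.
#' @export
setMethod("[[", "GeneSetCollection", function(x, i, j, ...) {
  if (is.character(i)) {
    k <- match(i, setNamesOf(x))
    if (is.na(k)) stop("no gene set named '", i, "'", call. = FALSE)
    i <- k
  }
  x@sets[[i]]
})

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix: %d genes x %d samples\n",
              nrow(object@assay), ncol(object@assay)))
  cat("samples:", paste(head(colnames(object@assay), 6L), collapse = ", "),
      if (ncol(object@assay) > 6L) "..." else "", "\n")
})

setMethod("show", "LogExpressionMatrix", function(object) {
  cat(sprintf("LogExpressionMatrix [%s]: %d genes x %d units\n",
              object@spaceTag, nrow(object@assay), ncol(object@assay)))
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s' (%d genes)\n", object@name,
              length(object@members)))
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection with %d set(s)\n", length(object@sets)))
  for (s in head(object@sets, 8L))
    cat(sprintf("  %s: %d genes\n", s@name, length(s@members)))
  if (length(object@sets) > 8L) cat("  ...\n")
})

setMethod("show", "ComparisonResult", function(object) {
  tab <- table(factor(object@genes$call, c("up", "down", "none")))
  cat(sprintf("ComparisonResult: %s vs %s (PI level %.2f)\n",
              object@testLabel, object@controlLabel, object@piLevel))
  cat(sprintf("  %d genes: %d up, %d down, %d unchanged\n",
              nrow(object@genes), tab[["up"]], tab[["down"]],
              tab[["none"]]))
  cat(sprintf("  fit: slope %.3f, intercept %.3f, residual sd %.3f\n",
              object@fit$slope, object@fit$intercept,
              object@fit$residualSd))
})

setMethod("show", "SsgseaScores", function(object) {
  cat(sprintf("SsgseaScores: %d unit(s) x %d set(s), alpha = %g\n",
              nrow(object@scores), ncol(object@scores), object@alpha))
})

setMethod("show", "KmCurve", function(object) {
  fmt <- function(v) if (is.na(v)) "NA" else format(v)
  cat(sprintf("KmCurve '%s': %d event time(s); median %s, 95%% CI [%s, %s]\n",
              object@group, length(object@time), fmt(object@median),
              fmt(object@medianLower), fmt(object@medianUpper)))
})

#' Construct a gene set or a collection
#'
#' @param name set name (non-empty string).
#' @param members character vector of gene ids; duplicates are removed.
#' @param description optional free-text description.
#' @return \code{geneSet}: a [GeneSet-class]; \code{geneSetCollection}: a
#'   [GeneSetCollection-class].
#' @examples
#' gs <- geneSet("MES1", c("CHI3L1", "CD44"))
#' geneSetCollection(list(gs))
#' @export
geneSet <- function(name, members, description = "") {
  new("GeneSet", name = as.character(name),
      description = as.character(description),
      members = unique(as.character(members)))
}

#' @rdname geneSet
#' @param sets list of [GeneSet-class] objects with unique names.
#' @export
geneSetCollection <- function(sets) {
  new("GeneSetCollection", sets = as.list(sets))
}

#' Construct a count matrix container
#'
#' @param assay numeric matrix of non-negative integer counts with gene
#'   rownames and sample colnames.
#' @return a validated [CountMatrix-class].
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2,
#'             dimnames = list(c("TP53", "EGFR"), c("s1", "s2")))
#' countMatrix(m)
#' @export
countMatrix <- function(assay) {
  storage.mode(assay) <- "double"
  new("CountMatrix", assay = assay)
}
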