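## Readers and writers for every external table the pipeline touches.
## Canonical dialect: TSV, UTF-8, Unix newlines, header cell "gene" for
## matrices. Readers validate strictly and fail with the offending
## location; they never impute.

.fmtStop <- function(path, ...) {
  stop(sprintf("%s: %s", path, sprintf(...)), call. = FALSE)
}

.readTsvLines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (!length(lines)) .fmtStop(path, "empty file")
  strsplit(lines, "\t", fixed = TRUE)
}

.parseMatrixTsv <- function(path, integer_only) {
  rows <- .readTsvLines(path)
  header <- rows[[1L]]
  if (length(header) < 2L)
    .fmtStop(path, "header must contain a gene column and >= 1 sample")
  samples <- header[-1L]
  body <- rows[-1L]
  if (!length(body)) .fmtStop(path, "no gene rows found")
  genes <- vapply(body, `[`, character(1L), 1L)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    .fmtStop(path, "duplicated gene id(s): %s", paste(dup, collapse = ", "))
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    .fmtStop(path, "duplicated sample id(s): %s",
             paste(dup, collapse = ", "))
  vals <- matrix(NA_real_, length(body), length(samples),
                 dimnames = list(genes, samples))
  for (i in seq_along(body)) {
    r <- body[[i]]
    if (length(r) != length(header))
      .fmtStop(path, "row %d ('%s') has %d fields, expected %d",
               i + 1L, r[1L], length(r), length(header))
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      .fmtStop(path, "non-numeric value '%s' at row %d ('%s'), column '%s'",
               r[j + 1L], i + 1L, r[1L], samples[j])
    }
    if (any(v < 0)) {
      j <- which(v < 0)[1L]
      .fmtStop(path, "negative value %s at row %d ('%s'), column '%s'",
               format(v[j]), i + 1L, r[1L], samples[j])
    }
    if (integer_only && any(v != floor(v))) {
      j <- which(v != floor(v))[1L]
      .fmtStop(path, "non-integer count %s at row %d ('%s'), column '%s'",
               format(v[j]), i + 1L, r[1L], samples[j])
    }
    vals[i, ] <- v
  }
  vals
}

#' Read and write count matrices
#'
#' \code{readCounts} reads a TSV whose header row holds sample ids (first
#' header cell \code{"gene"}), whose first column holds gene ids, and
#' whose cells hold non-negative integer read counts. Input gene and
#' sample order is preserved. \code{writeCounts} writes the canonical
#' form; \code{writeCounts(readCounts(p), p2)} reproduces a canonical
#' input byte-for-byte.
#'
#' @param path file path of the TSV.
#' @return \code{readCounts}: a [CountMatrix-class].
#' @examples
#' p <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "TP53\t5\t2", "EGFR\t0\t7"), p)
#' readCounts(p)
#' @export
readCounts <- function(path) {
  countMatrix(.parseMatrixTsv(path, integer_only = TRUE))
}

.writeMatrixTsv <- function(m, path, fmt = function(x) format(x, trim = TRUE,
                                                              scientific = FALSE)) {
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = "\t"), character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname readCounts
#' @param x a [CountMatrix-class].
#' @export
writeCounts <- function(x, path) {
  stopifnot(is(x, "CountMatrix"))
  .writeMatrixTsv(assayValues(x), path)
}

#' Read and write log2(CPM+1) expression matrices
#'
#' Same TSV dialect as [readCounts()] but with real-valued cells; values
#' must be non-negative and finite since they live on the log2(CPM+1)
#' scale.
#'
#' @param path file path of the TSV.
#' @param digits significant digits written (default 15, round-trip safe).
#' @return \code{readExpression}: a [LogExpressionMatrix-class].
#' @export
readExpression <- function(path) {
  new("LogExpressionMatrix",
      assay = .parseMatrixTsv(path, integer_only = FALSE),
      spaceTag = "log2cpm")
}

#' @rdname readExpression
#' @param x a [LogExpressionMatrix-class].
#' @export
writeExpression <- function(x, path, digits = 15L) {
  stopifnot(is(x, "LogExpressionMatrix"))
  .writeMatrixTsv(assayValues(x), path,
                  fmt = function(v) formatC(v, digits = digits,
                                            format = "g"))
}

#' Read gene sets from a GMT file
#'
#' Broad-dialect GMT: one set per line, tab-separated as
#' \code{name TAB description TAB member...}. Duplicate members within a
#' line are removed with a warning; duplicate set names across lines are
#' an error.
#'
#' @param path file path of the GMT.
#' @return a [GeneSetCollection-class], one set per line, input order.
#' @examples
#' p <- tempfile(fileext = ".gmt")
#' writeLines("MES1\tmesenchymal\tCHI3L1\tCD44", p)
#' readGmt(p)
#' @export
readGmt <- function(path) {
  rows <- .readTsvLines(path)
  sets <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) < 3L)
      .fmtStop(path, "line %d has %d tab-separated field(s), expected >= 3",
               i, length(r))
    mem <- r[-(1:2)]
    mem <- mem[nzchar(mem)]
    if (anyDuplicated(mem)) {
      warning(sprintf("%s: line %d ('%s'): duplicated member(s) %s removed",
                      path, i, r[1L],
                      paste(unique(mem[duplicated(mem)]), collapse = ", ")),
              call. = FALSE)
      mem <- unique(mem)
    }
    if (!length(mem))
      .fmtStop(path, "line %d ('%s') has no members", i, r[1L])
    sets[[i]] <- geneSet(r[1L], mem, r[2L])
  }
  nms <- vapply(sets, function(s) s@name, character(1L))
  if (anyDuplicated(nms))
    .fmtStop(path, "duplicated set name(s): %s",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
  geneSetCollection(sets)
}

#' @rdname readGmt
#' @param x a [GeneSetCollection-class].
#' @export
writeGmt <- function(x, path) {
  stopifnot(is(x, "GeneSetCollection"))
  lines <- vapply(x@sets, function(s)
    paste(c(s@name, s@description, s@members), collapse = "\t"),
    character(1L))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read and write survival tables
#'
#' TSV with columns \code{sample}, \code{time} (days, >= 0) and
#' \code{event} (1 = death observed, 0 = censored). Sample ids must be
#' unique.
#'
#' @param path file path of the TSV.
#' @return \code{readSurvival}: a data.frame with columns \code{sample}
#'   (character), \code{time} (numeric) and \code{event} (integer 0/1).
#' @export
readSurvival <- function(path) {
  rows <- .readTsvLines(path)
  header <- rows[[1L]]
  need <- c("sample", "time", "event")
  miss <- setdiff(need, header)
  if (length(miss))
    .fmtStop(path, "missing column(s): %s", paste(miss, collapse = ", "))
  idx <- match(need, header)
  body <- rows[-1L]
  if (!length(body)) .fmtStop(path, "no records")
  out <- data.frame(
    sample = vapply(body, `[`, character(1L), idx[1L]),
    time = suppressWarnings(as.numeric(vapply(body, `[`, character(1L),
                                              idx[2L]))),
    event = suppressWarnings(as.numeric(vapply(body, `[`, character(1L),
                                               idx[3L]))),
    stringsAsFactors = FALSE)
  validateSurvival(out, path)
}

#' @rdname readSurvival
#' @param surv a survival data.frame as returned by \code{readSurvival}.
#' @param context label used in error messages (defaults to
#'   \code{"survival table"}).
#' @export
validateSurvival <- function(surv, context = "survival table") {
  if (!all(c("sample", "time", "event") %in% names(surv)))
    .fmtStop(context, "missing column(s)")
  if (anyNA(surv$time) || anyNA(surv$event))
    .fmtStop(context, "non-numeric time or event value")
  bad <- which(surv$time < 0)
  if (length(bad))
    .fmtStop(context, "negative time %s for sample '%s'",
             format(surv$time[bad[1L]]), surv$sample[bad[1L]])
  bad <- which(!surv$event %in% c(0, 1))
  if (length(bad))
    .fmtStop(context, "event value %s for sample '%s' not in {0,1}",
             format(surv$event[bad[1L]]), surv$sample[bad[1L]])
  dup <- unique(surv$sample[duplicated(surv$sample)])
  if (length(dup))
    .fmtStop(context, "duplicated sample id(s): %s",
             paste(dup, collapse = ", "))
  surv$event <- as.integer(surv$event)
  surv
}

#' @rdname readSurvival
#' @export
writeSurvival <- function(surv, path) {
  surv <- validateSurvival(surv)
  lines <- c("sample\ttime\tevent",
             sprintf("%s\t%s\t%d", surv$sample,
                     vapply(surv$time, format, character(1L),
                            trim = TRUE, scientific = FALSE),
                     surv$event))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
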