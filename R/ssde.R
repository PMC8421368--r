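## Replicate-free single-sample differential expression.
##
## With one test and one control transcriptome and no replicates, the
## usual dispersion-based tests are unavailable. Instead, one global
## ordinary-least-squares regression of the test sample on the control
## sample is fitted over all genes, and each gene's test value is
## compared with the prediction interval of the fitted line evaluated at
## that gene's control value: genes far outside the interval, and changed
## by more than one log2 unit, are called differentially expressed.

#' Ordinary least squares of test on control expression
#'
#' Fits \code{y = intercept + slope * x} by least squares over all genes,
#' with \code{x} the control sample's log2(CPM+1) values and \code{y} the
#' test sample's. The residual standard deviation uses \code{n - 2}
#' degrees of freedom.
#'
#' @param control,test numeric vectors of equal length (>= 3), one value
#'   per gene, on the log2(CPM+1) scale.
#' @return list with elements \code{slope}, \code{intercept}, \code{n},
#'   \code{xMean}, \code{sxx} (sum of squared x deviations),
#'   \code{residualSd} and \code{df} (= n - 2).
#' @examples
#' f <- fitRegression(c(1, 2, 3, 4, 5), c(1.1, 1.9, 3.2, 3.8, 5.1))
#' f$slope
#' @export
fitRegression <- function(control, test) {
  x <- as.numeric(control)
  y <- as.numeric(test)
  n <- length(x)
  if (length(y) != n) stop("control and test lengths differ", call. = FALSE)
  if (n < 3L) stop("at least 3 genes are required to fit", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing expression values", call. = FALSE)
  xbar <- mean(x)
  sxx <- sum((x - xbar)^2)
  if (sxx == 0)
    stop("degenerate input: control sample is constant (sxx = 0)",
         call. = FALSE)
  slope <- sum((x - xbar) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * xbar
  sse <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, n = n, xMean = xbar,
       sxx = sxx, residualSd = sqrt(max(sse, 0) / (n - 2L)), df = n - 2L)
}

#' Prediction interval of the fitted regression
#'
#' Two-sided t-based interval for a single new observation at control
#' value \code{x}:
#' \code{predicted +/- t(1-(1-level)/2, n-2) * s * sqrt(1 + 1/n +
#' (x - xbar)^2 / sxx)}. The unit residual-variance term makes it wider
#' than the confidence interval of the line, which is what a single
#' unreplicated observation requires.
#'
#' @param fit regression summary from [fitRegression()].
#' @param x numeric vector of control values at which to predict.
#' @param level coverage probability in (0,1); default 0.99.
#' @return data.frame with columns \code{predicted}, \code{pi_lower},
#'   \code{pi_upper}, one row per element of \code{x}.
#' @export
predictionInterval <- function(fit, x, level = 0.99) {
  if (length(level) != 1L || is.na(level) || level <= 0 || level >= 1)
    stop("level must be a single probability in (0,1)", call. = FALSE)
  pred <- fit$intercept + fit$slope * x
  half <- qt(1 - (1 - level) / 2, df = fit$df) * fit$residualSd *
    sqrt(1 + 1 / fit$n + (x - fit$xMean)^2 / fit$sxx)
  data.frame(predicted = pred, pi_lower = pred - half,
             pi_upper = pred + half)
}

.asLogVector <- function(x, sample, what) {
  if (!is(x, "LogExpressionMatrix"))
    stop(what, " must be a LogExpressionMatrix (log2cpm-tagged); ",
         "run normalizeCounts() first", call. = FALSE)
  a <- assayValues(x)
  if (is.null(sample)) {
    if (ncol(a) != 1L)
      stop(what, " has ", ncol(a), " columns; name the sample to use",
           call. = FALSE)
    sample <- colnames(a)
  }
  if (!sample %in% colnames(a))
    stop("no sample '", sample, "' in ", what, call. = FALSE)
  setNames(a[, sample], rownames(a))
}

#' Call differentially expressed genes without replicates
#'
#' Fits the global test-on-control regression ([fitRegression()]),
#' evaluates the prediction interval at every gene's control value, and
#' calls a gene \emph{up} iff its test value exceeds the upper interval
#' bound \emph{and} test - control > \code{delta_threshold} (log2), or
#' \emph{down} under the mirrored conditions. Each gene also receives a
#' z-score \code{|predicted - test| / sd_used} with
#' \code{sd_used = |(predicted - upperPI)/2|}, i.e. half the one-sided
#' interval width; when the interval collapses (zero residual variance)
#' the z-score is 0 for a perfectly predicted gene and \code{Inf}
#' otherwise.
#'
#' @param control,test [LogExpressionMatrix-class] objects holding the
#'   control and test transcriptome (the tag guards against feeding raw
#'   counts or double-transformed values).
#' @param control_sample,test_sample column to use from each matrix;
#'   defaults to the only column.
#' @param pi_level prediction-interval coverage; default 0.99.
#' @param delta_threshold minimum |log2 difference| required in addition
#'   to the interval exceedance; default 1.
#' @return a [ComparisonResult-class]; gene order follows the control
#'   input.
#' @examples
#' set.seed(1)
#' sim <- simulateCountPair(n_genes = 300, n_planted_up = 5, seed = 1)
#' res <- callGenes(normalizeCounts(sim$control), normalizeCounts(sim$test))
#' res
#' @export
callGenes <- function(control, test, control_sample = NULL,
                      test_sample = NULL, pi_level = 0.99,
                      delta_threshold = 1) {
  x <- .asLogVector(control, control_sample, "control")
  y <- .asLogVector(test, test_sample, "test")
  if (!identical(sort(names(x)), sort(names(y))))
    stop("control and test gene sets differ; refusing to intersect",
         call. = FALSE)
  y <- y[names(x)]
  fit <- fitRegression(x, y)
  pi <- predictionInterval(fit, x, level = pi_level)
  delta <- unname(y - x)
  up <- y > pi$pi_upper & delta > delta_threshold
  down <- y < pi$pi_lower & delta < -delta_threshold
  call <- ifelse(up, "up", ifelse(down, "down", "none"))
  sd_used <- abs((pi$predicted - pi$pi_upper) / 2)
  z <- ifelse(sd_used > 0, abs((pi$predicted - y) / sd_used),
              ifelse(pi$predicted == y, 0, Inf))
  genes <- data.frame(gene = names(x), control = unname(x),
                      test = unname(y), predicted = pi$predicted,
                      pi_lower = pi$pi_lower, pi_upper = pi$pi_upper,
                      delta = delta, call = call, z_score = unname(z),
                      sd_used = sd_used, row.names = NULL,
                      stringsAsFactors = FALSE)
  new("ComparisonResult",
      testLabel = if (is.null(test_sample)) colnames(assayValues(test))
                  else test_sample,
      controlLabel = if (is.null(control_sample))
                       colnames(assayValues(control))
                     else control_sample,
      piLevel = pi_level, fit = fit, genes = genes)
}

#' Volcano table of a single-sample comparison
#'
#' One row per gene with the log2 difference, the z-score used in place
#' of -log10(p) on the volcano y-axis, and the call. Rows are ordered by
#' decreasing |z| (an infinite z sorts first), ties broken by gene id, so
#' the output is stable across runs and input orderings.
#'
#' @param result a [ComparisonResult-class].
#' @return data.frame with columns \code{gene}, \code{delta},
#'   \code{z_score}, \code{call}.
#' @export
volcanoTable <- function(result) {
  stopifnot(is(result, "ComparisonResult"))
  g <- result@genes
  out <- g[order(-g$z_score, g$gene),
           c("gene", "delta", "z_score", "call")]
  rownames(out) <- NULL
  out
}
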