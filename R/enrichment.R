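## Preranked GSEA, single-sample GSEA, cluster averaging and meta-module
## labelling.

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Rank genes of a comparison for preranked GSEA
#'
#' Ranking metric = sign(delta) * z_score, mirroring the volcano-plot
#' convention of this replicate-free method (the z-score replaces
#' -log10 p). Genes are ordered by decreasing metric; ties (including
#' all-zero metrics) are broken lexicographically by gene id so the
#' ranking is deterministic.
#'
#' @param result a [ComparisonResult-class].
#' @return data.frame with columns \code{gene} and \code{metric}, sorted.
#' @export
rankGenes <- function(result) {
  stopifnot(is(result, "ComparisonResult"))
  g <- result@genes
  if (!nrow(g)) stop("empty comparison result", call. = FALSE)
  metric <- sign(g$delta) * g$z_score
  metric[g$z_score == 0] <- 0        # sign(0) * 0 kept as exact zero
  out <- data.frame(gene = g$gene, metric = metric,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$metric, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Weighted Kolmogorov-Smirnov running sum: +|metric|^w (normalised) at
## in-set positions, -1/(N - Nh) elsewhere; ES is the signed maximum
## deviation. `hits` are positions in the ranked list.
.gseaES <- function(absMetric, hits, weight) {
  N <- length(absMetric)
  Nh <- length(hits)
  w <- absMetric[hits]^weight
  sw <- sum(w)
  if (sw == 0) { w <- rep(1, Nh); sw <- Nh }  # all-zero metrics: flat hits
  steps <- rep(-1 / (N - Nh), N)
  steps[hits] <- w / sw
  run <- cumsum(steps)
  run[which.max(abs(run))]
}

#' Preranked gene set enrichment analysis
#'
#' Computes the classic weighted Kolmogorov-Smirnov enrichment score for
#' each gene set against a ranked list, with gene-label permutations for
#' the normalised enrichment score (NES), nominal p and FDR q. Hit
#' increments are proportional to |metric|^weight (normalised to sum 1
#' over in-set genes); miss decrements are 1/(N - set size). The NES
#' divides the ES by the mean |permuted ES| of the same sign; the nominal
#' p is the fraction of all permutations at least as extreme in the
#' observed direction (no pseudo-count, so exhaustive enumeration yields
#' the exact fraction); the FDR q compares the observed NES with the
#' pooled permuted NES distribution in the standard way.
#'
#' @param ranked data.frame from [rankGenes()] (columns \code{gene},
#'   \code{metric}, sorted by decreasing metric).
#' @param sets a [GeneSetCollection-class].
#' @param weight exponent on |metric| for hit increments; default 1.
#' @param n_perm number of gene-label permutations, or the string
#'   \code{"all"} for exhaustive enumeration over all C(N, set size)
#'   placements (only sensible for tiny lists).
#' @param seed integer seed for the permutations (ignored for
#'   \code{"all"}); the caller's RNG state is left untouched.
#' @param min_size,max_size sets with fewer/more members present in the
#'   ranked list are skipped with a warning; defaults 5 and 2000.
#' @return data.frame with one row per scored set: \code{set},
#'   \code{size}, \code{es}, \code{nes}, \code{nominal_p}, \code{fdr_q},
#'   \code{n_perm}. Skipped sets are absent.
#' @export
gseaPreranked <- function(ranked, sets, weight = 1, n_perm = 1000,
                          seed = 1L, min_size = 5L, max_size = 2000L) {
  stopifnot(is(sets, "GeneSetCollection"),
            all(c("gene", "metric") %in% names(ranked)))
  if (any(diff(ranked$metric) > 0))
    stop("ranked metric must be in decreasing order", call. = FALSE)
  N <- nrow(ranked)
  absMetric <- abs(ranked$metric)
  exhaustive <- identical(n_perm, "all")

  scoreOne <- function(gs) {
    hits <- which(ranked$gene %in% members(gs))
    Nh <- length(hits)
    if (Nh == 0L) {
      warning("set '", gs@name, "' has no overlap with the ranked list; ",
              "skipped", call. = FALSE)
      return(NULL)
    }
    if (Nh < min_size || Nh > max_size || Nh == N) {
      warning("set '", gs@name, "' has ", Nh, " gene(s) in the list, ",
              "outside [", min_size, ", ", min(max_size, N - 1L),
              "]; skipped", call. = FALSE)
      return(NULL)
    }
    es <- .gseaES(absMetric, hits, weight)
    if (exhaustive) {
      placements <- utils::combn(N, Nh)
      permES <- apply(placements, 2L, function(h)
        .gseaES(absMetric, h, weight))
    } else {
      permES <- vapply(seq_len(n_perm), function(i)
        .gseaES(absMetric, sort(sample.int(N, Nh)), weight), numeric(1L))
    }
    list(name = gs@name, size = Nh, es = es, permES = permES)
  }

  scored <- .withSeed(if (exhaustive) NULL else seed,
                      lapply(sets@sets, scoreOne))
  scored <- scored[!vapply(scored, is.null, logical(1L))]
  if (!length(scored))
    return(data.frame(set = character(0), size = integer(0),
                      es = numeric(0), nes = numeric(0),
                      nominal_p = numeric(0), fdr_q = numeric(0),
                      n_perm = integer(0)))

  normalise <- function(es, permES) {
    m <- if (es >= 0) mean(permES[permES >= 0]) else -mean(permES[permES < 0])
    if (!is.finite(m) || m == 0) NA_real_ else es / m
  }
  nes <- vapply(scored, function(s) normalise(s$es, s$permES), numeric(1L))
  # ties between mathematically equal ES values can differ in the last
  # float bit across placements; count them as extreme
  pval <- vapply(scored, function(s) {
    if (s$es >= 0) mean(s$permES >= s$es - 1e-12)
    else mean(s$permES <= s$es + 1e-12)
  }, numeric(1L))
  permNES <- lapply(scored, function(s) {
    pos <- s$permES[s$permES >= 0]
    neg <- s$permES[s$permES < 0]
    c(if (length(pos) && mean(pos) > 0) pos / mean(pos),
      if (length(neg)) -neg / mean(-neg) * -1)
  })
  poolNES <- unlist(permNES)
  obsNES <- nes
  fdr <- vapply(seq_along(scored), function(i) {
    v <- obsNES[i]
    if (is.na(v)) return(NA_real_)
    if (v >= 0) {
      num <- mean(poolNES[poolNES >= 0] >= v)
      den <- mean(obsNES[!is.na(obsNES) & obsNES >= 0] >= v)
    } else {
      num <- mean(poolNES[poolNES < 0] <= v)
      den <- mean(obsNES[!is.na(obsNES) & obsNES < 0] <= v)
    }
    if (is.nan(num)) num <- 0
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1L))
  data.frame(set = vapply(scored, `[[`, character(1L), "name"),
             size = vapply(scored, `[[`, numeric(1L), "size"),
             es = vapply(scored, `[[`, numeric(1L), "es"),
             nes = nes, nominal_p = pval, fdr_q = fdr,
             n_perm = if (exhaustive)
               vapply(scored, function(s) length(s$permES), numeric(1L))
             else n_perm,
             stringsAsFactors = FALSE)
}

#' Single-sample GSEA score of one expression profile
#'
#' Rank-based signature score: genes are ordered by decreasing
#' expression; walking down the ranking, the in-set empirical CDF
#' (weighted by rank^alpha, higher expression = larger rank value) minus
#' the out-of-set empirical CDF is accumulated, and the score is the sum
#' of the differences over all positions. Being a function of ranks only,
#' the score is invariant under strictly monotone transforms of the
#' profile, so CPM, TPM or their logs give identical scores.
#'
#' @param profile named numeric vector, one expression value per gene.
#' @param set a [GeneSet-class]; at least one member must be present.
#' @param alpha rank-weight exponent; default 0.25.
#' @return single numeric score.
#' @examples
#' p <- c(g1 = 9, g2 = 7, g3 = 5, g4 = 3, g5 = 2, g6 = 1)
#' ssgseaScore(p, geneSet("S", c("g1", "g2")))
#' @export
ssgseaScore <- function(profile, set, alpha = 0.25) {
  stopifnot(is(set, "GeneSet"))
  if (is.null(names(profile)) || anyDuplicated(names(profile)))
    stop("profile must be named with unique gene ids", call. = FALSE)
  N <- length(profile)
  ord <- order(-profile, names(profile))     # decreasing, id tie-break
  inset <- names(profile)[ord] %in% members(set)
  Nh <- sum(inset)
  if (Nh == 0L)
    stop("set '", set@name, "' shares no genes with the profile",
         call. = FALSE)
  if (Nh == N)
    stop("set '", set@name, "' covers the whole profile", call. = FALSE)
  rankValue <- N - seq_len(N) + 1           # top gene gets rank N
  w <- ifelse(inset, rankValue^alpha, 0)
  ecdfIn <- cumsum(w) / sum(w)
  ecdfOut <- cumsum(!inset) / (N - Nh)
  sum(ecdfIn - ecdfOut)
}

#' Single-sample GSEA scores for many units and sets
#'
#' Applies [ssgseaScore()] to every column (unit: bulk sample, cell,
#' cluster mean, or spatial feature) against every set of a collection.
#'
#' @param expr a [LogExpressionMatrix-class] or a plain genes-by-units
#'   numeric matrix (the score depends on within-unit ranks only).
#' @param sets a [GeneSetCollection-class].
#' @param alpha rank-weight exponent; default 0.25.
#' @param normalize if TRUE, divide all scores by the overall score range
#'   across units and sets (useful when comparing heterogeneous units);
#'   default FALSE (raw scores).
#' @return an [SsgseaScores-class] (units x sets).
#' @export
ssgseaScores <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  a <- if (is(expr, "LogExpressionMatrix")) assayValues(expr) else expr
  stopifnot(is.matrix(a), is(sets, "GeneSetCollection"))
  units <- colnames(a)
  nms <- setNamesOf(sets)
  scores <- matrix(NA_real_, length(units), length(nms),
                   dimnames = list(units, nms))
  for (j in seq_along(sets@sets))
    for (u in seq_along(units))
      scores[u, j] <- ssgseaScore(setNames(a[, u], rownames(a)),
                                  sets@sets[[j]], alpha = alpha)
  if (normalize) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  new("SsgseaScores", scores = scores, alpha = alpha)
}

#' Average single-cell expression within clusters
#'
#' Arithmetic mean of each gene over the cells of each cluster, giving
#' one profile per cluster.
#'
#' @param expr a [LogExpressionMatrix-class] (genes x cells) or plain
#'   matrix.
#' @param cell_to_cluster named character vector mapping every cell
#'   (column) to a cluster.
#' @return numeric matrix, genes x clusters (cluster name order =
#'   first-appearance order).
#' @export
averageClusters <- function(expr, cell_to_cluster) {
  a <- if (is(expr, "LogExpressionMatrix")) assayValues(expr) else expr
  stopifnot(is.matrix(a))
  unknown <- setdiff(names(cell_to_cluster), colnames(a))
  if (length(unknown))
    stop("label(s) for unknown cell(s): ",
         paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
  miss <- setdiff(colnames(a), names(cell_to_cluster))
  if (length(miss))
    stop("unlabelled cell(s): ", paste(head(miss, 5L), collapse = ", "),
         call. = FALSE)
  cl <- cell_to_cluster[colnames(a)]
  out <- t(rowsum(t(a), group = cl, reorder = FALSE))
  sweep(out, 2L, as.vector(table(cl)[colnames(out)]), "/")
}

#' Assign each cell to its top-scoring meta-module
#'
#' Argmax of the per-cell ssGSEA scores across module sets; a cell whose
#' maximum is attained by more than one module is left
#' \code{"unassigned"}.
#'
#' @param scores an [SsgseaScores-class] with cells as units and module
#'   sets as columns.
#' @return named character vector, cell -> module (or "unassigned").
#' @export
assignCellModules <- function(scores) {
  stopifnot(is(scores, "SsgseaScores"))
  m <- scoreMatrix(scores)
  vapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    top <- which(v == max(v))
    if (length(top) != 1L) "unassigned" else colnames(m)[top]
  }, character(1L)) |> setNames(rownames(m))
}

#' Label clusters by their cells' meta-modules
#'
#' Majority rule: a cluster is labelled with a module only when more than
#' 50% of its cells carry that module, otherwise \code{"unassigned"}.
#' Max-frequency rule: the modal module labels the cluster; a tie for the
#' mode gives \code{"unassigned"}. Cells whose own module is
#' "unassigned" count toward the cluster size but never provide the
#' label.
#'
#' @param cell_modules named character vector, cell -> module.
#' @param cell_to_cluster named character vector, cell -> cluster; must
#'   cover exactly the same cells.
#' @param rule \code{"majority"} (default) or \code{"max-frequency"}.
#' @return list with \code{cluster_to_module} (named character vector),
#'   \code{rule_used}, and the input \code{cell_to_cluster}.
#' @export
assignClusterLabels <- function(cell_modules, cell_to_cluster,
                                rule = c("majority", "max-frequency")) {
  rule <- match.arg(rule)
  if (!identical(sort(names(cell_modules)), sort(names(cell_to_cluster))))
    stop("cell_modules and cell_to_cluster cover different cells",
         call. = FALSE)
  cl <- unique(cell_to_cluster)
  lab <- vapply(cl, function(k) {
    mods <- cell_modules[names(cell_to_cluster)[cell_to_cluster == k]]
    if (!length(mods)) stop("empty cluster '", k, "'", call. = FALSE)
    counts <- table(mods[mods != "unassigned"])
    if (!length(counts)) return("unassigned")
    if (rule == "majority") {
      if (max(counts) / length(mods) > 0.5)
        names(counts)[which.max(counts)] else "unassigned"
    } else {
      top <- names(counts)[counts == max(counts)]
      if (length(top) == 1L) top else "unassigned"
    }
  }, character(1L))
  list(cluster_to_module = setNames(lab, cl), rule_used = rule,
       cell_to_cluster = cell_to_cluster)
}
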