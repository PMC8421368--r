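## Synthetic-data generators.
##
## Every generator is deterministic given (parameters, seed) and returns
## the planted truth alongside the data, so each pipeline stage can be
## tested against known ground truth without any external download. The
## generative caricature is the standard RNA-seq one: gene-wise lognormal
## baseline abundances and negative-binomial counts.

.checkSeed <- function(seed) {
  if (is.null(seed) || is.na(seed) || length(seed) != 1L)
    stop("an explicit integer seed is required", call. = FALSE)
  as.integer(seed)
}

#' Simulate a paired control/test bulk count profile
#'
#' Baseline log2 relative abundances are drawn from a normal (i.e. the
#' abundances are lognormal), scaled to the library size to give
#' per-gene negative-binomial means; test means equal control means
#' shifted by the planted log2 effects. With \code{dispersion = 0} the
#' counts are the deterministically rounded means (a noise-free pair).
#'
#' @param n_genes number of genes (>= 100).
#' @param n_planted_up,n_planted_down number of genes planted with
#'   +\code{effect} / -\code{effect} log2 shifts; defaults 50 and 0.
#' @param effect planted |log2| effect size; default 3.
#' @param effects optional named numeric vector of per-gene log2 effects
#'   overriding the counts above; names must exist in the gene universe.
#' @param plant_high if TRUE (default) planted genes are chosen among
#'   high-expression genes (baseline CPM >= \code{high_cpm}).
#' @param high_cpm CPM floor defining "high expression"; default 100.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion);
#'   default 0.1. 0 gives deterministic rounded means.
#' @param library_size per-sample expected total counts; default 2e7.
#' @param baseline_mean,baseline_sd normal parameters of the baseline
#'   log2 relative abundance; defaults 4 and 2 (a broad lognormal).
#' @param seed integer seed (required).
#' @return list with \code{control} and \code{test}
#'   ([CountMatrix-class], single sample each) and \code{truth} (seed,
#'   planted effect vectors, dispersion, library sizes, baseline means).
#' @examples
#' sim <- simulateCountPair(n_genes = 200, n_planted_up = 5, seed = 42)
#' sim$truth$planted_up
#' @export
simulateCountPair <- function(n_genes = 5000L, n_planted_up = 50L,
                              n_planted_down = 0L, effect = 3,
                              effects = NULL, plant_high = TRUE,
                              high_cpm = 100, dispersion = 0.1,
                              library_size = 2e7,
                              baseline_mean = 4, baseline_sd = 2,
                              seed) {
  seed <- .checkSeed(seed)
  if (n_genes < 100L) stop("n_genes must be >= 100", call. = FALSE)
  .withSeed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    log2rel <- rnorm(n_genes, baseline_mean, baseline_sd)
    p <- 2^log2rel / sum(2^log2rel)
    muC <- p * library_size
    eff <- setNames(numeric(n_genes), genes)
    if (!is.null(effects)) {
      unknown <- setdiff(names(effects), genes)
      if (length(unknown))
        stop("effects on unknown gene(s): ",
             paste(head(unknown, 5L), collapse = ", "), call. = FALSE)
      eff[names(effects)] <- effects
    } else {
      pool <- if (plant_high) which(p * 1e6 >= high_cpm)
              else seq_len(n_genes)
      need <- n_planted_up + n_planted_down
      if (length(pool) < need)
        stop("only ", length(pool), " gene(s) eligible for planting, ",
             need, " needed", call. = FALSE)
      chosen <- sample(pool, need)
      eff[chosen[seq_len(n_planted_up)]] <- effect
      if (n_planted_down > 0L)
        eff[chosen[n_planted_up + seq_len(n_planted_down)]] <- -effect
    }
    muT <- muC * 2^eff
    draw <- function(mu) {
      if (dispersion == 0) round(mu)
      else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    }
    mk <- function(v, label) countMatrix(matrix(v, ncol = 1L,
                                                dimnames = list(genes,
                                                                label)))
    list(control = mk(draw(muC), "control"),
         test = mk(draw(muT), "test"),
         truth = list(seed = seed,
                      planted_up = names(eff)[eff > 0],
                      planted_down = names(eff)[eff < 0],
                      effects = eff[eff != 0],
                      baseline_cpm = setNames(p * 1e6, genes),
                      dispersion = dispersion,
                      library_sizes = c(control = library_size,
                                        test = library_size)))
  })
}

#' Simulate single cells organised in module-labelled clusters
#'
#' Each cluster is planted with one glioblastoma meta-module; a fixed
#' fraction \code{purity} of the cluster's cells (rounded up) carries
#' that module, the rest carry other modules drawn uniformly — so
#' purity is the exact in-module cell fraction that the majority
#' labelling rule operates on, and any purity above 0.5 keeps the
#' planted module in the majority by construction. A cell's expression
#' is a gene-wise
#' baseline plus Gaussian noise, with \code{shift} added on the cell's
#' own module genes; values are floored at 0 to stay in log2(CPM+1)
#' space.
#'
#' @param n_cells total cells, divided evenly over the clusters.
#' @param modules a [GeneSetCollection-class] of module signatures.
#' @param n_background_genes non-signature genes added to the universe;
#'   default 100.
#' @param purity fraction of each cluster's cells carrying the planted
#'   module (rounded up per cluster), in (0, 1]; default 1.
#' @param shift additive log2 shift on a cell's module genes; default 3.
#' @param noise_sd Gaussian noise sd; default 1.
#' @param baseline_mean,baseline_sd gene baseline parameters; defaults 5
#'   and 1.
#' @param seed integer seed (required).
#' @return list with \code{expr} ([LogExpressionMatrix-class], genes x
#'   cells), \code{cell_to_cluster}, \code{cell_modules} (the true
#'   per-cell module), and \code{truth} (cluster -> module map, purity,
#'   shift, noise_sd, seed).
#' @export
simulateSingleCells <- function(n_cells = 200L, modules,
                                n_background_genes = 100L, purity = 1,
                                shift = 3, noise_sd = 1,
                                baseline_mean = 5, baseline_sd = 1,
                                seed) {
  seed <- .checkSeed(seed)
  stopifnot(is(modules, "GeneSetCollection"))
  if (purity <= 0 || purity > 1)
    stop("purity must be in (0, 1]", call. = FALSE)
  modNames <- setNamesOf(modules)
  if (length(modNames) < 2L)
    stop("at least 2 modules are required", call. = FALSE)
  .withSeed(seed, {
    sigGenes <- unique(unlist(lapply(modules@sets, members)))
    genes <- c(sigGenes,
               sprintf("bg%04d", seq_len(n_background_genes)))
    clusters <- paste0("cluster", seq_along(modNames))
    clusterModule <- setNames(modNames, clusters)
    cellCluster <- setNames(
      rep(clusters, length.out = n_cells)[sample.int(n_cells)],
      sprintf("cell%04d", seq_len(n_cells)))
    cellModule <- setNames(character(n_cells), names(cellCluster))
    for (k in clusters) {
      cells <- names(cellCluster)[cellCluster == k]
      nIn <- ceiling(purity * length(cells))
      own <- if (nIn >= length(cells)) cells else sample(cells, nIn)
      cellModule[own] <- clusterModule[[k]]
      rest <- setdiff(cells, own)
      if (length(rest))
        cellModule[rest] <- sample(setdiff(modNames, clusterModule[[k]]),
                                   length(rest), replace = TRUE)
    }
    baseline <- rnorm(length(genes), baseline_mean, baseline_sd)
    a <- matrix(rnorm(length(genes) * n_cells, 0, noise_sd),
                length(genes), n_cells,
                dimnames = list(genes, names(cellCluster))) + baseline
    for (ci in seq_len(n_cells)) {
      mem <- members(modules[[cellModule[[ci]]]])
      a[mem, ci] <- a[mem, ci] + shift
    }
    a <- pmax(a, 0)
    list(expr = new("LogExpressionMatrix", assay = a,
                    spaceTag = "log2cpm"),
         cell_to_cluster = cellCluster,
         cell_modules = cellModule,
         truth = list(seed = seed, cluster_modules = clusterModule,
                      purity = purity, shift = shift,
                      noise_sd = noise_sd))
  })
}

#' Simulate spatial feature expression profiles
#'
#' Per-gene baseline means constant across anatomic features, plus
#' Gaussian feature noise, plus a planted shift for each feature's
#' marker genes in that feature only.
#'
#' @param features character vector of feature ids (>= 2); defaults to
#'   the eight glioblastoma anatomic features used by the niche map.
#' @param n_genes non-marker genes; default 200.
#' @param markers_per_feature planted marker genes per feature; default
#'   5.
#' @param shift planted log2 shift of a marker in its feature; default
#'   3 (i.e. 3 noise-sd units at the default \code{noise_sd = 1}).
#' @param noise_sd feature-level Gaussian noise sd; default 1. Use 0 for
#'   noise-free profiles.
#' @param baseline_mean,baseline_sd gene baseline parameters; defaults 5
#'   and 1.
#' @param seed integer seed (required).
#' @return list with \code{profile} (genes x features matrix) and
#'   \code{truth} (feature -> marker map, shift, noise_sd, seed).
#' @export
simulateSpatialProfiles <- function(features = c("LE", "IT", "CT",
                                                 "CT_control", "PAN",
                                                 "PNZ_ccGSC", "MVP",
                                                 "HBV_ccGSC"),
                                    n_genes = 200L,
                                    markers_per_feature = 5L, shift = 3,
                                    noise_sd = 1, baseline_mean = 5,
                                    baseline_sd = 1, seed) {
  seed <- .checkSeed(seed)
  if (length(features) < 2L)
    stop("at least 2 features are required", call. = FALSE)
  .withSeed(seed, {
    markers <- setNames(lapply(seq_along(features), function(i)
      sprintf("mk_%s_%02d", features[i], seq_len(markers_per_feature))),
      features)
    genes <- c(unlist(markers), sprintf("g%04d", seq_len(n_genes)))
    baseline <- rnorm(length(genes), baseline_mean, baseline_sd)
    prof <- matrix(rnorm(length(genes) * length(features), 0, noise_sd),
                   length(genes), length(features),
                   dimnames = list(genes, features)) + baseline
    for (f in features) prof[markers[[f]], f] <- prof[markers[[f]], f] +
        shift
    prof <- pmax(prof, 0)
    list(profile = prof,
         truth = list(seed = seed, feature_markers = markers,
                      shift = shift, noise_sd = noise_sd))
  })
}

## Uniform censoring horizon giving the requested overall censor rate
## against an Exp(h) event time: solves (1 - exp(-hU)) / (hU) = rate.
.censorHorizon <- function(h, rate) {
  stats::uniroot(function(U) (1 - exp(-h * U)) / (h * U) - rate,
                 lower = 1e-8 / h, upper = 1e6 / h, tol = 1e-10)$root
}

#' Simulate a median-split stratified survival cohort
#'
#' Four groups named by the cross of two dichotomised signature scores
#' (\code{lowA_highB}, \code{lowA_lowB}, \code{highA_highB},
#' \code{highA_lowB}), each with exponential event times at its own
#' hazard and optional independent uniform censoring. The two score
#' columns are drawn uniformly from disjoint low/high bands, so
#' [stratifyByScoreMedians()] on the generated scores reproduces the
#' planted groups exactly (equal group sizes put both medians between
#' the bands).
#'
#' @param n_per_group samples per group; default 200.
#' @param hazards named numeric vector of 4 positive hazards (per day)
#'   for \code{lowA_highB}, \code{lowA_lowB}, \code{highA_highB},
#'   \code{highA_lowB}. Default: median survivals of roughly 3500 / 1400
#'   / 1400 / 600 days, the prognosis ordering expected when score A
#'   tracks the hydrogel-culture signature and score B the stem-cell
#'   signature.
#' @param censor_rate expected fraction censored, in [0, 1); default
#'   0.2.
#' @param seed integer seed (required).
#' @return list with \code{survival} (data.frame sample/time/event),
#'   \code{scores} ([SsgseaScores-class] with sets "3D-GMH list" and
#'   "GSC list"), \code{groups} (named character vector, the planted
#'   group per sample) and \code{truth}.
#' @export
simulateSurvival <- function(n_per_group = 200L,
                             hazards = c(lowA_highB = log(2) / 3500,
                                         lowA_lowB = log(2) / 1400,
                                         highA_highB = log(2) / 1400,
                                         highA_lowB = log(2) / 600),
                             censor_rate = 0.2, seed) {
  seed <- .checkSeed(seed)
  need <- c("lowA_highB", "lowA_lowB", "highA_highB", "highA_lowB")
  if (!all(need %in% names(hazards)) || length(hazards) != 4L)
    stop("hazards must be named: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(hazards <= 0)) stop("hazards must be positive", call. = FALSE)
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  .withSeed(seed, {
    groups <- rep(need, each = n_per_group)
    ids <- sprintf("s%04d", seq_along(groups))
    t_event <- rexp(length(groups), rate = hazards[groups])
    if (censor_rate > 0) {
      horizon <- vapply(hazards, .censorHorizon, numeric(1L),
                        rate = censor_rate)
      t_cens <- runif(length(groups), 0, horizon[groups])
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, length(groups))
      time <- t_event
    }
    lowBand <- function() runif(n_per_group * 2L, 0.0, 0.4)
    highBand <- function() runif(n_per_group * 2L, 0.6, 1.0)
    a <- b <- numeric(length(groups))
    a[grepl("^lowA", groups)] <- lowBand()
    a[grepl("^highA", groups)] <- highBand()
    b[grepl("highB$", groups)] <- highBand()
    b[grepl("lowB$", groups)] <- lowBand()
    scores <- new("SsgseaScores",
                  scores = matrix(c(a, b), ncol = 2L,
                                  dimnames = list(ids, c("3D-GMH list",
                                                         "GSC list"))),
                  alpha = 0.25)
    list(survival = data.frame(sample = ids, time = time,
                               event = event, stringsAsFactors = FALSE),
         scores = scores,
         groups = setNames(groups, ids),
         truth = list(seed = seed, hazards = hazards,
                      censor_rate = censor_rate,
                      n_per_group = n_per_group))
  })
}
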