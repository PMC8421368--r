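#' Pipeline configuration
#'
#' Bundles the tunable constants of the pipeline with their defaults:
#' 99% prediction intervals, a 1-log2-unit fold-change threshold, ssGSEA
#' exponent 0.25, GSEA weight 1 with 1000 permutations and set-size
#' bounds [5, 2000], spatial z threshold 1, and median ties going to
#' "low".
#'
#' @param pi_level prediction-interval coverage in (0,1).
#' @param delta_threshold log2 fold-change threshold (> 0).
#' @param ssgsea_alpha ssGSEA rank-weight exponent (>= 0).
#' @param gsea_weight,gsea_min_size,gsea_max_size,gsea_n_perm,gsea_seed
#'   preranked-GSEA settings.
#' @param spatial_z_threshold minimum z for a spatial assignment (> 0).
#' @return named list of validated settings, class "pipelineConfig".
#' @export
pipelineConfig <- function(pi_level = 0.99, delta_threshold = 1,
                           ssgsea_alpha = 0.25, gsea_weight = 1,
                           gsea_min_size = 5L, gsea_max_size = 2000L,
                           gsea_n_perm = 1000L, gsea_seed = 1L,
                           spatial_z_threshold = 1) {
  stopifnot(pi_level > 0, pi_level < 1, delta_threshold > 0,
            ssgsea_alpha >= 0, gsea_min_size >= 1,
            gsea_max_size >= gsea_min_size, gsea_n_perm >= 1,
            spatial_z_threshold > 0)
  structure(list(pi_level = pi_level, delta_threshold = delta_threshold,
                 ssgsea_alpha = ssgsea_alpha, gsea_weight = gsea_weight,
                 gsea_min_size = gsea_min_size,
                 gsea_max_size = gsea_max_size,
                 gsea_n_perm = gsea_n_perm, gsea_seed = gsea_seed,
                 spatial_z_threshold = spatial_z_threshold),
            class = "pipelineConfig")
}

.demoModules <- function() {
  mods <- c("MES1like", "MES2like", "AClike", "OPClike")
  geneSetCollection(lapply(mods, function(m)
    geneSet(m, sprintf("%s_g%02d", m, 1:30),
            "synthetic demo module")))
}

#' End-to-end demonstration pipeline on synthetic data
#'
#' Simulates every input, runs the full analysis — normalisation,
#' replicate-free differential calls, consensus-list compilation,
#' preranked GSEA, single-cell ssGSEA scoring and cluster labelling,
#' spatial niche assignment, and median-split survival stratification —
#' and writes the outputs plus a plain-text report comparing what the
#' pipeline recovered with what was planted. The run is fully
#' deterministic: the same seed reproduces the report byte-for-byte.
#'
#' @param seed integer master seed; per-stage seeds are derived from it.
#' @param outdir output directory (must be creatable/writable); files
#'   are only written after all stages have completed.
#' @param config a [pipelineConfig()].
#' @param n_genes,n_cells,n_per_group problem sizes of the simulated
#'   inputs; defaults keep the demo under a few seconds.
#' @return invisibly, a list with the per-stage results and a logical
#'   vector \code{checks} of truth-recovery outcomes; the report is
#'   written to \code{file.path(outdir, "report.txt")}.
#' @examples
#' \donttest{
#' res <- runDemo(seed = 7, outdir = tempfile("demo"))
#' res$checks
#' }
#' @export
runDemo <- function(seed = 7L, outdir, config = pipelineConfig(),
                    n_genes = 2000L, n_cells = 200L,
                    n_per_group = 150L) {
  seed <- .checkSeed(seed)
  stage <- "setup"
  report <- character(0)
  checks <- logical(0)
  say <- function(...) report <<- c(report, sprintf(...))
  check <- function(name, ok) {
    checks[[name]] <<- ok
    say("  [%s] %s", if (ok) "ok" else "FAIL", name)
  }
  out <- tryCatch({
    say("gliomaNiche demo pipeline (package version %s, seed %d)",
        as.character(utils::packageVersion("gliomaNiche")), seed)

    stage <- "ssde"
    say("## Replicate-free differential expression")
    sims <- vector("list", 3L)
    sims[[1L]] <- simulateCountPair(n_genes = n_genes,
                                    n_planted_up = 25L, seed = seed + 1L)
    for (k in 2:3)   # same planted genes in every comparison
      sims[[k]] <- simulateCountPair(n_genes = n_genes,
                                     effects = sims[[1L]]$truth$effects,
                                     seed = seed + k)
    results <- lapply(sims, function(s)
      callGenes(normalizeCounts(s$control), normalizeCounts(s$test),
                pi_level = config$pi_level,
                delta_threshold = config$delta_threshold))
    up1 <- geneIds(results[[1L]])[results[[1L]]@genes$call == "up"]
    hit <- mean(sims[[1L]]$truth$planted_up %in% up1)
    say("  comparison 1: %d genes called up; %.0f%% of planted effects",
        length(up1), 100 * hit)
    check("planted up-regulated genes recovered (>= 90%)", hit >= 0.9)

    stage <- "consensus"
    say("## Consensus gene list (3 comparisons)")
    shared <- Reduce(intersect, lapply(sims, function(s)
      s$truth$planted_up))
    flags <- lapply(results, comparisonFlags,
                    delta_threshold = config$delta_threshold)
    consensus <- compileConsensusList(flags)
    say("  %d genes in the consensus list", length(consensus$members))
    check("consensus list contains genes planted in all comparisons",
          length(shared) == 0 || mean(shared %in% consensus$members) >=
            0.9)

    stage <- "gsea"
    say("## Preranked GSEA")
    ranked <- rankGenes(results[[1L]])
    plantedSet <- geneSet("planted_up", sims[[1L]]$truth$planted_up)
    decoy <- geneSet("decoy",
                     setdiff(ranked$gene,
                             sims[[1L]]$truth$planted_up)[1:25])
    gsea <- gseaPreranked(ranked, geneSetCollection(list(plantedSet,
                                                         decoy)),
                          weight = config$gsea_weight, n_perm = 500,
                          seed = seed, min_size = config$gsea_min_size,
                          max_size = config$gsea_max_size)
    esP <- gsea$es[gsea$set == "planted_up"]
    say("  planted set: ES %.3f, NES %.3f, p %.4f",
        esP, gsea$nes[gsea$set == "planted_up"],
        gsea$nominal_p[gsea$set == "planted_up"])
    check("planted set enriched at top of ranking (ES > 0.5, p < 0.05)",
          esP > 0.5 && gsea$nominal_p[gsea$set == "planted_up"] < 0.05)

    stage <- "single-cell"
    say("## Single-cell ssGSEA and cluster labelling")
    modules <- .demoModules()
    sc <- simulateSingleCells(n_cells = n_cells, modules = modules,
                              purity = 0.8, seed = seed + 11L)
    cellScores <- ssgseaScores(sc$expr, modules,
                               alpha = config$ssgsea_alpha)
    cellMods <- assignCellModules(cellScores)
    lab <- assignClusterLabels(cellMods, sc$cell_to_cluster,
                               rule = "majority")
    agree <- mean(lab$cluster_to_module[names(sc$truth$cluster_modules)]
                  == sc$truth$cluster_modules)
    say("  %d clusters labelled; %.0f%% match the planted modules",
        length(lab$cluster_to_module), 100 * agree)
    check("majority-rule cluster labels match planted modules",
          agree == 1)

    stage <- "spatial"
    say("## Spatial niche assignment")
    sp <- simulateSpatialProfiles(seed = seed + 23L)
    assign <- assignSpatialFeatures(sp$profile,
                                    z_threshold =
                                      config$spatial_z_threshold)
    truthFeat <- unlist(lapply(names(sp$truth$feature_markers),
                               function(f)
      setNames(rep(f, length(sp$truth$feature_markers[[f]])),
               sp$truth$feature_markers[[f]])))
    got <- assign$assigned_feature[match(names(truthFeat), assign$gene)]
    rec <- mean(got == truthFeat)
    say("  %.0f%% of planted markers assigned to their feature", 100 *
          rec)
    check("planted spatial markers recovered (>= 90%)", rec >= 0.9)

    stage <- "survival"
    say("## Median-split survival stratification")
    sv <- simulateSurvival(n_per_group = n_per_group,
                           seed = seed + 31L)
    strat <- stratifyByScoreMedians(sv$scores, sv$survival)
    check("median split reproduces the planted groups",
          identical(strat$group, unname(sv$groups[strat$sample])))
    curves <- lapply(split(strat, strat$group), kmFit)
    for (g in names(curves))
      curves[[g]]@group <- g
    med <- vapply(curves, function(k) k@median, numeric(1L))
    lr <- logrankTest(split(strat[, c("sample", "time", "event")],
                            strat$group))
    for (g in names(med))
      say("  %s: median survival %.0f days", g, med[g])
    say("  log-rank chi-square %.1f (df %d), p %.3g", lr$chi_square,
        lr$df, lr$p_value)
    check("best-prognosis group outlives worst (lowA_highB > highA_lowB)",
          is.finite(med["lowA_highB"]) && is.finite(med["highA_lowB"]) &&
            med["lowA_highB"] > med["highA_lowB"])

    say("## Summary: %d/%d checks passed", sum(checks), length(checks))
    list(results = results, consensus = consensus, gsea = gsea,
         clusterLabels = lab, spatial = assign, stratification = strat,
         curves = curves, logrank = lr)
  }, error = function(e) {
    stop("demo failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outdir, call. = FALSE)
  ok <- file.access(outdir, mode = 2L) == 0L
  if (!ok) stop("output directory not writable: ", outdir, call. = FALSE)
  writeLines(report, file.path(outdir, "report.txt"))
  utils::write.table(volcanoTable(out$results[[1L]]),
                     file.path(outdir, "volcano_comparison1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(out$consensus$members,
             file.path(outdir, "consensus_list.txt"))
  utils::write.table(out$gsea, file.path(outdir, "gsea.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$spatial, file.path(outdir, "spatial.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(out$stratification,
                     file.path(outdir, "stratification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(out, list(checks = checks, report = report)))
}
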