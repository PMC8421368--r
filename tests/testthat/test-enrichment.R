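# Ranking, preranked GSEA, ssGSEA and cluster machinery.

test_that("gene ranking applies sign(delta) * z with id tie-break", {
  mk_result <- function(genes, delta, z) {
    new("ComparisonResult", testLabel = "t", controlLabel = "c",
        piLevel = 0.99, fit = list(slope = 1, intercept = 0,
                                   residualSd = 1),
        genes = data.frame(gene = genes, control = 0, test = delta,
                           predicted = 0, pi_lower = -10, pi_upper = 10,
                           delta = delta, call = "none", z_score = z,
                           sd_used = 1, stringsAsFactors = FALSE))
  }
  r <- rankGenes(mk_result(c("A", "B"), c(2, -1.5), c(5, 4)))
  expect_identical(r$gene, c("A", "B"))
  expect_equal(r$metric, c(5, -4))

  r0 <- rankGenes(mk_result(c("c", "a", "b"), c(0, 0, 0), c(0, 0, 0)))
  expect_identical(r0$gene, c("a", "b", "c"))

  # determinism under shuffling
  set.seed(1)
  res <- mk_result(sprintf("g%02d", 1:20), rnorm(20), abs(rnorm(20)))
  perm <- sample(20)
  res_p <- res
  res_p@genes <- res@genes[perm, ]
  expect_equal(rankGenes(res), rankGenes(res_p))
})

test_that("single-member sets give the extreme enrichment scores", {
  ranked <- data.frame(gene = sprintf("g%02d", 1:10),
                       metric = seq(5, -4))
  gs1 <- geneSetCollection(list(geneSet("first", "g01")))
  gs10 <- geneSetCollection(list(geneSet("last", "g10")))
  r1 <- gseaPreranked(ranked, gs1, weight = 0, n_perm = "all",
                      min_size = 1)
  r10 <- gseaPreranked(ranked, gs10, weight = 0, n_perm = "all",
                       min_size = 1)
  expect_equal(r1$es, 1)
  expect_equal(r10$es, -1)
  expect_equal(r1$nominal_p, 1 / 10)   # only the top placement ties it
})

test_that("ES and exact p equal exhaustive enumeration for small lists", {
  set.seed(31)
  for (rep in 1:5) {
    N <- sample(8:12, 1)
    k <- sample(2:3, 1)
    metric <- sort(round(rnorm(N, 0, 2), 2), decreasing = TRUE)
    genes <- sprintf("g%02d", 1:N)
    hit <- sort(sample(N, k))
    ranked <- data.frame(gene = genes, metric = metric)
    gs <- geneSetCollection(list(geneSet("S", genes[hit])))
    got <- gseaPreranked(ranked, gs, weight = 1, n_perm = "all",
                         min_size = k)
    want <- oracle_exact_p(metric, hit, weight = 1)
    expect_equal(got$es, want$es, tolerance = 1e-12)
    expect_equal(got$nominal_p, want$p, tolerance = 1e-12)
    expect_identical(got$n_perm, choose(N, k))
    # weight 0 as well
    got0 <- gseaPreranked(ranked, gs, weight = 0, n_perm = "all",
                          min_size = k)
    want0 <- oracle_exact_p(metric, hit, weight = 0)
    expect_equal(got0$es, want0$es, tolerance = 1e-12)
    expect_equal(got0$nominal_p, want0$p, tolerance = 1e-12)
  }
})

test_that("ES is bounded and antisymmetric under ranking reversal", {
  set.seed(17)
  for (rep in 1:20) {
    N <- sample(20:60, 1)
    k <- sample(3:8, 1)
    metric <- sort(rnorm(N), decreasing = TRUE)
    genes <- sprintf("g%02d", 1:N)
    hit <- sort(sample(N, k))
    ranked <- data.frame(gene = genes, metric = metric)
    gs <- geneSetCollection(list(geneSet("S", genes[hit])))
    es <- gseaPreranked(ranked, gs, weight = 0, n_perm = 10,
                        min_size = 1)$es
    expect_lte(abs(es), 1)
    rev_ranked <- data.frame(gene = rev(genes), metric = rev(-metric))
    es_rev <- gseaPreranked(rev_ranked, gs, weight = 0, n_perm = 10,
                            min_size = 1)$es
    expect_equal(es_rev, -es, tolerance = 1e-12)
  }
})

test_that("preranked ES agrees with the fgsea reference", {
  set.seed(23)
  N <- 200
  genes <- sprintf("g%03d", 1:N)
  metric <- sort(rnorm(N, 0, 2), decreasing = TRUE)
  stats <- setNames(metric, genes)
  mem <- sample(genes, 25)
  ranked <- data.frame(gene = genes, metric = metric)
  got <- gseaPreranked(ranked, geneSetCollection(list(geneSet("S", mem))),
                       weight = 1, n_perm = 10)
  want <- fgsea::calcGseaStat(stats, selectedStats = which(genes %in% mem),
                              gseaParam = 1)
  expect_equal(got$es, want, tolerance = 1e-6)
})

test_that("permutation results are seeded and reproducible", {
  set.seed(99)
  N <- 100
  genes <- sprintf("g%03d", 1:N)
  ranked <- data.frame(gene = genes,
                       metric = sort(rnorm(N), decreasing = TRUE))
  gs <- geneSetCollection(list(geneSet("S", sample(genes, 10))))
  a <- gseaPreranked(ranked, gs, n_perm = 200, seed = 5)
  b <- gseaPreranked(ranked, gs, n_perm = 200, seed = 5)
  expect_identical(a, b)
  expect_warning(
    gseaPreranked(ranked,
                  geneSetCollection(list(geneSet("none", "absent"))),
                  n_perm = 10),
    "no overlap")
  expect_warning(
    gseaPreranked(ranked,
                  geneSetCollection(list(geneSet("tiny", genes[1:2]))),
                  n_perm = 10),
    "skipped")
})

test_that("ssGSEA equals the brute-force partial-ECDF oracle", {
  p <- c(g1 = 9, g2 = 7, g3 = 5, g4 = 3, g5 = 2, g6 = 1)
  s <- geneSet("S", c("g1", "g2"))
  expect_equal(ssgseaScore(p, s), oracle_ssgsea(p, members(s), 0.25),
               tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:10) {
    prof <- setNames(rnorm(50, 5, 2), sprintf("g%02d", 1:50))
    mem <- sample(names(prof), sample(3:12, 1))
    alpha <- sample(c(0, 0.25, 1), 1)
    expect_equal(ssgseaScore(prof, geneSet("S", mem), alpha = alpha),
                 oracle_ssgsea(prof, mem, alpha), tolerance = 1e-10)
  }
})

test_that("ssGSEA is rank-based and sensitive to member position", {
  set.seed(12)
  prof <- setNames(runif(30, 1, 10), sprintf("g%02d", 1:30))
  s <- geneSet("S", sample(names(prof), 5))
  base <- ssgseaScore(prof, s)
  expect_equal(ssgseaScore(2^prof, s), base, tolerance = 1e-12)
  expect_equal(ssgseaScore(rank(prof), s), base, tolerance = 1e-12)

  # one member moved from top rank to bottom strictly lowers the score
  prof2 <- sort(prof, decreasing = TRUE)
  s2 <- geneSet("S2", names(prof2)[c(1, 10, 20)])
  lowered <- prof2
  lowered[names(prof2)[1]] <- min(prof2) - 1
  expect_lt(ssgseaScore(lowered, s2), ssgseaScore(prof2, s2))

  expect_error(ssgseaScore(prof, geneSet("none", "absent")),
               "no genes")
})

test_that("cluster averaging equals an independent group-by mean", {
  set.seed(6)
  a <- matrix(rnorm(20 * 30), 20,
              dimnames = list(sprintf("g%02d", 1:20),
                              sprintf("c%02d", 1:30)))
  cl <- setNames(sample(c("k1", "k2", "k3"), 30, TRUE), colnames(a))
  got <- averageClusters(a, cl)
  for (k in unique(cl))
    expect_equal(got[, k], rowMeans(a[, names(cl)[cl == k],
                                      drop = FALSE]),
                 tolerance = 1e-12)
  # singleton cluster equals the cell itself
  cl1 <- cl
  cl1[1] <- "solo"
  expect_equal(averageClusters(a, cl1)[, "solo"], a[, 1],
               tolerance = 1e-15)
  expect_error(averageClusters(a, cl[-1]), "unlabelled")
  expect_error(averageClusters(a, c(cl, ghost = "k1")), "unknown cell")
})

test_that("cluster labelling rules follow their truth tables", {
  cells <- sprintf("c%02d", 1:10)
  cl <- setNames(rep("k1", 10), cells)
  mods <- setNames(c(rep("MES1", 6), rep("AC", 4)), cells)
  expect_identical(
    assignClusterLabels(mods, cl, "majority")$cluster_to_module[["k1"]],
    "MES1")
  tie <- setNames(c(rep("MES1", 5), rep("AC", 5)), cells)
  expect_identical(
    assignClusterLabels(tie, cl, "majority")$cluster_to_module[["k1"]],
    "unassigned")
  expect_identical(
    assignClusterLabels(tie, cl,
                        "max-frequency")$cluster_to_module[["k1"]],
    "unassigned")
  # max-frequency labels a plurality that majority refuses
  plur <- setNames(c(rep("MES1", 4), rep("AC", 3), rep("OPC", 3)),
                   cells)
  expect_identical(
    assignClusterLabels(plur, cl, "majority")$cluster_to_module[["k1"]],
    "unassigned")
  expect_identical(
    assignClusterLabels(plur, cl,
                        "max-frequency")$cluster_to_module[["k1"]],
    "MES1")
  homo <- setNames(rep("NPC1", 10), cells)
  for (rule in c("majority", "max-frequency"))
    expect_identical(
      assignClusterLabels(homo, cl, rule)$cluster_to_module[["k1"]],
      "NPC1")
})

test_that("planted module signatures score above size-matched decoys", {
  mods <- geneSetCollection(lapply(c("MES1", "AC", "OPC"), function(m)
    geneSet(m, sprintf("%s_%02d", m, 1:25))))
  sc <- simulateSingleCells(n_cells = 120, modules = mods, purity = 1,
                            shift = 3, seed = 77)
  a <- assayValues(sc$expr)
  set.seed(78)
  margin <- vapply(colnames(a), function(cell) {
    prof <- setNames(a[, cell], rownames(a))
    own <- sc$cell_modules[[cell]]
    decoy <- geneSet("decoy", sample(rownames(a), 25))
    ssgseaScore(prof, mods[[own]]) - ssgseaScore(prof, decoy)
  }, numeric(1))
  expect_gt(mean(margin > 0), 0.95)
  expect_gt(mean(margin), 0)
})
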