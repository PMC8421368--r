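# Generators: reproducibility, validator compliance, planted structure.

test_that("generators are exactly reproducible from (parameters, seed)", {
  a <- simulateCountPair(n_genes = 150, n_planted_up = 5, seed = 3)
  b <- simulateCountPair(n_genes = 150, n_planted_up = 5, seed = 3)
  expect_identical(assayValues(a$control), assayValues(b$control))
  expect_identical(assayValues(a$test), assayValues(b$test))
  expect_identical(a$truth, b$truth)
  c <- simulateCountPair(n_genes = 150, n_planted_up = 5, seed = 4)
  expect_false(identical(assayValues(a$control), assayValues(c$control)))

  mods <- geneSetCollection(list(geneSet("A", paste0("a", 1:10)),
                                 geneSet("B", paste0("b", 1:10))))
  s1 <- simulateSingleCells(50, mods, seed = 5)
  s2 <- simulateSingleCells(50, mods, seed = 5)
  expect_identical(assayValues(s1$expr), assayValues(s2$expr))

  sp1 <- simulateSpatialProfiles(seed = 6)
  sp2 <- simulateSpatialProfiles(seed = 6)
  expect_identical(sp1$profile, sp2$profile)

  sv1 <- simulateSurvival(n_per_group = 20, seed = 7)
  sv2 <- simulateSurvival(n_per_group = 20, seed = 7)
  expect_identical(sv1$survival, sv2$survival)
  expect_error(simulateCountPair(n_genes = 150), "seed")
})

test_that("generated objects satisfy the package validators", {
  sim <- simulateCountPair(n_genes = 150, n_planted_up = 5, seed = 11)
  expect_true(validObject(sim$control))
  expect_true(validObject(sim$test))
  mods <- geneSetCollection(list(geneSet("A", paste0("a", 1:10)),
                                 geneSet("B", paste0("b", 1:10))))
  sc <- simulateSingleCells(40, mods, seed = 12)
  expect_true(validObject(sc$expr))
  sv <- simulateSurvival(n_per_group = 15, seed = 13)
  expect_true(validObject(sv$scores))
  expect_silent(validateSurvival(sv$survival))
  # survival table survives a round trip through the TSV reader
  p <- withr::local_tempfile(fileext = ".tsv")
  writeSurvival(sv$survival, p)
  rt <- readSurvival(p)
  expect_identical(rt$sample, sv$survival$sample)
  expect_identical(rt$event, sv$survival$event)
})

test_that("a dispersion-zero no-effect pair is an exact null", {
  sim <- simulateCountPair(n_genes = 150, n_planted_up = 0,
                           dispersion = 0, seed = 21)
  expect_identical(unname(assayValues(sim$control)),
                   unname(assayValues(sim$test)))
})

test_that("planted effects land on the named genes only", {
  sim <- simulateCountPair(n_genes = 150,
                           effects = c(g00005 = 3, g00007 = -2),
                           seed = 22, dispersion = 0)
  lg <- function(m) log2(assayValues(m) + 1)
  d <- lg(sim$test) - lg(sim$control)
  expect_gt(d["g00005", 1], 2.5)
  expect_lt(d["g00007", 1], -1.5)
  expect_lt(max(abs(d[setdiff(rownames(d), c("g00005", "g00007")), ])),
            0.2)
  expect_error(simulateCountPair(n_genes = 150,
                                 effects = c(ghost = 3), seed = 1),
               "unknown gene")
})

test_that("pure-module cells put their planted module on top", {
  mods <- geneSetCollection(lapply(c("MES1", "AC", "OPC"), function(m)
    geneSet(m, sprintf("%s_%02d", m, 1:20))))
  sc <- simulateSingleCells(n_cells = 60, modules = mods, purity = 1,
                            shift = 3, noise_sd = 0.3, seed = 31)
  top <- assignCellModules(ssgseaScores(sc$expr, mods))
  expect_identical(unname(top), unname(sc$cell_modules[names(top)]))
  expect_true(all(unname(top[names(sc$cell_to_cluster)]) ==
                    sc$truth$cluster_modules[sc$cell_to_cluster]))
  expect_error(simulateSingleCells(60, mods, purity = 0, seed = 1),
               "purity")
})

test_that("spatial generator plants recoverable markers", {
  sp <- simulateSpatialProfiles(n_genes = 100, shift = 3, noise_sd = 0,
                                seed = 41)
  suppressMessages(a <- assignSpatialFeatures(sp$profile))
  for (f in names(sp$truth$feature_markers)) {
    mk <- sp$truth$feature_markers[[f]]
    expect_true(all(a$assigned_feature[match(mk, a$gene)] == f))
  }
  expect_error(simulateSpatialProfiles(features = "only_one", seed = 1),
               "at least 2")
})

test_that("survival generator matches its closed forms", {
  # censoring-free single-hazard group: empirical median ~ ln 2 / h
  h <- log(2) / 1000
  sv <- simulateSurvival(n_per_group = 400,
                         hazards = c(lowA_highB = h, lowA_lowB = h,
                                     highA_highB = h, highA_lowB = h),
                         censor_rate = 0, seed = 51)
  k <- kmFit(sv$survival)
  expect_equal(k@median, 1000, tolerance = 0.15)  # Monte-Carlo band

  # requested censoring rate is honoured in expectation
  svc <- simulateSurvival(n_per_group = 400,
                          hazards = c(lowA_highB = h, lowA_lowB = h,
                                      highA_highB = h, highA_lowB = h),
                          censor_rate = 0.3, seed = 52)
  expect_equal(mean(svc$survival$event == 0), 0.3, tolerance = 0.12)

  # score bands reproduce the planted groups through the median split
  st <- stratifyByScoreMedians(svc$scores, svc$survival)
  expect_identical(st$group, unname(svc$groups[st$sample]))

  expect_error(simulateSurvival(hazards = c(a = 1), seed = 1), "named")
  expect_error(simulateSurvival(n_per_group = 10,
                                hazards = c(lowA_highB = -1,
                                            lowA_lowB = 1,
                                            highA_highB = 1,
                                            highA_lowB = 1), seed = 1),
               "positive")
})
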