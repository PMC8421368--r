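# Spatial niche assignment, survival machinery, cytokine fold changes.

test_that("spatial z-scores match a hand computation and the niche map", {
  feats <- c("LE", "IT", "CT", "CT_control", "PAN", "PNZ_ccGSC", "MVP",
             "HBV_ccGSC")
  v <- c(5.1, 4.9, 5.0, 5.2, 8.4, 5.3, 4.8, 5.0)
  prof <- matrix(v, 1, dimnames = list("geneX", feats))
  z <- spatialZscores(prof)
  expect_equal(unname(z[1, ]), (v - mean(v)) / sd(v), tolerance = 1e-12)
  a <- assignSpatialFeatures(prof)
  expect_identical(a$assigned_feature, "PAN")
  expect_identical(a$group, "Perinecrotic")

  # full feature -> group map
  for (pair in list(c("PNZ_ccGSC", "Perinecrotic"),
                    c("MVP", "Perivascular"),
                    c("HBV_ccGSC", "Perivascular"),
                    c("LE", "Tumor periphery"),
                    c("IT", "Tumor periphery"),
                    c("CT", "Tumor core"),
                    c("CT_control", "Tumor core"))) {
    w <- rep(1, 8)
    names(w) <- feats
    w[pair[1]] <- 9
    p1 <- matrix(w, 1, dimnames = list("g", feats))
    a1 <- assignSpatialFeatures(p1)
    expect_identical(a1$assigned_feature, pair[1])
    expect_identical(a1$group, pair[2])
  }
})

test_that("flat or sub-threshold profiles stay unassigned", {
  feats <- paste0("f", 1:4)
  prof <- rbind(flat = rep(2, 4), weak = c(2, 2, 3, 3))
  colnames(prof) <- feats
  expect_message(a <- assignSpatialFeatures(prof), "zero variance")
  expect_identical(a$assigned_feature, c("unassigned", "unassigned"))
  expect_true(is.na(a$max_z[1]))
  expect_equal(a$max_z[2], sqrt(3) / 2, tolerance = 1e-12)  # below 1
  a2 <- assignSpatialFeatures(prof, z_threshold = a$max_z[2] - 0.01)
  expect_identical(a2$assigned_feature[2], "f3")
  # unmapped feature names fall into the unassigned group
  expect_identical(a2$group[2], "unassigned")

  # two features: z is +/- the same magnitude
  p2 <- matrix(c(1, 3), 1, dimnames = list("g", c("A", "B")))
  z2 <- spatialZscores(p2)
  expect_equal(unname(z2[1, "A"]), -unname(z2[1, "B"]))
})

test_that("median-split stratification crosses the two dichotomies", {
  sc <- new("SsgseaScores",
            scores = matrix(c(0.1, 0.1, 0.9, 0.9, 0.1, 0.9, 0.1, 0.9),
                            4, 2,
                            dimnames = list(paste0("s", 1:4),
                                            c("A", "B"))),
            alpha = 0.25)
  surv <- data.frame(sample = paste0("s", 1:4), time = c(10, 20, 30, 40),
                     event = c(1L, 1L, 0L, 1L))
  st <- stratifyByScoreMedians(sc, surv)
  expect_identical(sort(st$group),
                   sort(c("lowA_lowB", "lowA_highB", "highA_lowB",
                          "highA_highB")))
  expect_identical(anyDuplicated(st$group), 0L)

  # a sample exactly at the median is "low"
  sc2 <- new("SsgseaScores",
             scores = matrix(c(0.1, 0.5, 0.9, 0.1, 0.5, 0.9), 3, 2,
                             dimnames = list(paste0("s", 1:3),
                                             c("A", "B"))),
             alpha = 0.25)
  surv3 <- data.frame(sample = paste0("s", 1:3), time = 1:3,
                      event = rep(1L, 3))
  st2 <- stratifyByScoreMedians(sc2, surv3)
  expect_identical(st2$group[st2$sample == "s2"], "lowA_lowB")

  # permutation invariance
  st3 <- stratifyByScoreMedians(sc, surv[c(3, 1, 4, 2), ])
  m <- match(st$sample, st3$sample)
  expect_identical(st$group, st3$group[m])

  expect_error(stratifyByScoreMedians(sc, rbind(surv,
    data.frame(sample = "s9", time = 5, event = 1L))),
    "without scores")
})

test_that("product-limit estimate matches the hand oracle", {
  # no censoring: empirical survivor function, median at second death
  k <- kmFit(data.frame(sample = letters[1:4], time = 1:4,
                        event = 1L))
  expect_equal(k@survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(k@median, 2)

  # toy censored set
  toy <- data.frame(sample = letters[1:5], time = 1:5,
                    event = c(1L, 0L, 1L, 0L, 1L))
  k2 <- kmFit(toy, group = "toy")
  o <- oracle_km(toy$time, toy$event)
  expect_equal(k2@time, o$time)
  expect_equal(k2@survival, o$surv, tolerance = 1e-12)
  expect_equal(k2@atRisk, o$n_risk)
  # Greenwood variance at each event time, by the textbook sum
  gw <- cumsum(o$n_event / (o$n_risk * (o$n_risk - o$n_event)))
  expect_equal(k2@greenwoodVar, o$surv^2 * gw, tolerance = 1e-12)

  all_cens <- data.frame(sample = letters[1:3], time = 1:3, event = 0L)
  k3 <- kmFit(all_cens)
  expect_true(is.na(k3@median))
  expect_true(is.na(k3@medianLower) && is.na(k3@medianUpper))
})

test_that("median CI matches the survival package construction", {
  set.seed(14)
  surv <- data.frame(sample = sprintf("s%03d", 1:80),
                     time = rexp(80, 1 / 500),
                     event = rbinom(80, 1, 0.8))
  k <- kmFit(surv)
  ref <- summary(survival::survfit(survival::Surv(time, event) ~ 1,
                                   data = surv,
                                   conf.type = "log-log"))$table
  expect_equal(k@medianLower, unname(ref["0.95LCL"]))
  expect_equal(k@medianUpper, unname(ref["0.95UCL"]))
  o <- oracle_km(surv$time, surv$event)
  expect_equal(k@median, min(o$time[o$surv <= 0.5]))
})

test_that("log-rank test matches the hand oracle and its contracts", {
  g1 <- data.frame(sample = paste0("a", 1:6),
                   time = c(2, 4, 6, 8, 10, 12),
                   event = c(1L, 1L, 0L, 1L, 1L, 0L))
  g2 <- data.frame(sample = paste0("b", 1:6),
                   time = c(1, 3, 5, 7, 9, 11),
                   event = c(1L, 1L, 1L, 1L, 0L, 1L))
  got <- logrankTest(list(A = g1, B = g2))
  want <- oracle_logrank2(g1$time, g1$event, g2$time, g2$event)
  expect_equal(got$chi_square, want, tolerance = 1e-8)
  expect_identical(got$df, 1L)

  twin <- logrankTest(list(A = g1, B = g1))
  # identical groups share every risk set, so O = E exactly
  expect_lt(twin$chi_square, 1e-10)
  expect_gt(twin$p_value, 0.999)

  expect_error(logrankTest(list(g1)), "at least 2")
  expect_error(logrankTest(list(A = g1, B = g2[0, ])), "empty group")
})

test_that("cytokine fold changes follow the densitometry rules", {
  tab <- data.frame(
    cytokine = rep(c("IL8", "CXCL1", "VEGFA"), each = 2),
    condition = rep(c("2D", "3D-GMH"), 3),
    mean_signal = c(100, 100, 50, 150, 30, 10),
    median_background = c(20, 20, 10, 10, 10, 20))
  fc <- cytokineFoldChange(tab, reference = "2D")
  il8 <- fc[fc$cytokine == "IL8", ]
  expect_equal(il8$corrected, 80)      # signal 100 - background 20
  expect_equal(il8$fold_change, 1)     # equal corrected intensities
  expect_equal(fc$fold_change[fc$cytokine == "CXCL1"], 140 / 40)
  # corrected <= 0 clipped to eps, ratio stays finite
  vegfa <- fc[fc$cytokine == "VEGFA", ]
  expect_equal(vegfa$corrected, 1e-6)
  expect_equal(vegfa$fold_change, 1e-6 / 20)
  expect_true(is.finite(vegfa$fold_change))

  expect_error(cytokineFoldChange(tab[tab$cytokine != "IL8" |
                                        tab$condition != "2D", ]),
               "missing in reference")
})
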