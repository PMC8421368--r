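## Anatomic-niche assignment, survival stratification and cytokine-array
## fold changes.

## Fixed anatomic feature -> niche group map: pseudopalisading/necrotic
## features are Perinecrotic, vascular features Perivascular, leading
## edge and infiltrating tumor the Tumor periphery, cellular tumor the
## Tumor core.
.featureGroups <- c(PAN = "Perinecrotic", PNZ_ccGSC = "Perinecrotic",
                    MVP = "Perivascular", HBV_ccGSC = "Perivascular",
                    LE = "Tumor periphery", IT = "Tumor periphery",
                    CT = "Tumor core", CT_control = "Tumor core")

#' Z-score genes across spatial features
#'
#' For each gene, standardises its mean log2 CPM profile across the
#' anatomic features: \code{z = (value - mean) / sd}, mean and sd taken
#' over features. Genes with zero variance across features get all-NA
#' z-scores (they carry no spatial information).
#'
#' @param profile numeric matrix, genes x features (>= 2 features), mean
#'   log2 CPM per feature.
#' @return numeric matrix of z-scores, same shape.
#' @export
spatialZscores <- function(profile) {
  stopifnot(is.matrix(profile), ncol(profile) >= 2L)
  mu <- rowMeans(profile)
  s <- apply(profile, 1L, sd)
  z <- (profile - mu) / s
  z[s == 0, ] <- NA_real_
  z
}

#' Assign genes to anatomic features and niche groups
#'
#' A gene is assigned to the feature where its across-feature z-score is
#' maximal, provided that maximum exceeds \code{z_threshold} (default 1);
#' otherwise it is left unassigned. Assigned features map onto four niche
#' groups via a fixed table: PAN and PNZ_ccGSC are Perinecrotic, MVP and
#' HBV_ccGSC Perivascular, LE and IT the Tumor periphery, CT and
#' CT_control the Tumor core. Genes with a flat profile (zero variance)
#' are unassigned and counted in a message, not an error.
#'
#' @param profile numeric matrix, genes x features.
#' @param z_threshold minimum z of the best feature; default 1.
#' @return data.frame with columns \code{gene}, \code{assigned_feature}
#'   ("unassigned" when below threshold), \code{max_z} (NA for flat
#'   profiles) and \code{group}.
#' @export
assignSpatialFeatures <- function(profile, z_threshold = 1) {
  z <- spatialZscores(profile)
  flat <- apply(z, 1L, function(v) all(is.na(v)))
  if (any(flat))
    message(sum(flat), " gene(s) with zero variance across features left",
            " unassigned")
  feat <- rep("unassigned", nrow(z))
  maxz <- rep(NA_real_, nrow(z))
  ok <- which(!flat)
  if (length(ok)) {
    best <- max.col(z[ok, , drop = FALSE], ties.method = "first")
    maxz[ok] <- z[cbind(ok, best)]
    pass <- maxz[ok] > z_threshold
    feat[ok[pass]] <- colnames(z)[best[pass]]
  }
  group <- ifelse(feat == "unassigned", "unassigned",
                  unname(.featureGroups[feat]))
  group[is.na(group)] <- "unassigned"
  data.frame(gene = rownames(profile), assigned_feature = feat,
             max_z = maxz, group = group, stringsAsFactors = FALSE)
}

#' Stratify samples by the medians of two signature scores
#'
#' Dichotomises each of two ssGSEA signature scores at its median over
#' the survival cohort (ties at the median go to "low"), and crosses the
#' two dichotomies into four groups: \code{lowA_lowB}, \code{lowA_highB},
#' \code{highA_lowB}, \code{highA_highB}. Score A is conventionally the
#' hydrogel-culture (3D-GMH) list and score B the stem-cell (GSC) list;
#' the patients of interest are then lowA_highB (best prognosis
#' expected) versus highA_lowB.
#'
#' @param scores an [SsgseaScores-class] with samples as units.
#' @param survival survival data.frame ([readSurvival()]); every sample
#'   must be scored on both sets.
#' @param set_a,set_b names of the two score columns; default the first
#'   two.
#' @return data.frame with columns \code{sample}, \code{score_a},
#'   \code{score_b}, \code{group}, \code{time}, \code{event}.
#' @export
stratifyByScoreMedians <- function(scores, survival,
                                   set_a = NULL, set_b = NULL) {
  stopifnot(is(scores, "SsgseaScores"))
  survival <- validateSurvival(survival)
  m <- scoreMatrix(scores)
  if (is.null(set_a)) set_a <- colnames(m)[1L]
  if (is.null(set_b)) set_b <- colnames(m)[2L]
  stopifnot(all(c(set_a, set_b) %in% colnames(m)))
  miss <- setdiff(survival$sample, rownames(m))
  if (length(miss))
    stop("sample(s) without scores: ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  a <- m[survival$sample, set_a]
  b <- m[survival$sample, set_b]
  ga <- ifelse(a <= median(a), "lowA", "highA")
  gb <- ifelse(b <= median(b), "lowB", "highB")
  data.frame(sample = survival$sample, score_a = unname(a),
             score_b = unname(b), group = paste(ga, gb, sep = "_"),
             time = survival$time, event = survival$event,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier product-limit fit for one group
#'
#' Product-limit survival estimate with Greenwood variance, median
#' survival (earliest time at which the curve falls to <= 0.5) and its
#' 95% confidence interval by the Brookmeyer-Crowley construction on the
#' log(-log) scale (the survival package's \code{conf.type = "log-log"});
#' an unbounded side is \code{NA}.
#'
#' @param surv survival data.frame ([readSurvival()]) for one group.
#' @param group label stored on the curve; default "all".
#' @return a [KmCurve-class]. Only times with at least one event appear.
#' @examples
#' kmFit(data.frame(sample = letters[1:4], time = 1:4, event = 1L))
#' @export
kmFit <- function(surv, group = "all") {
  surv <- validateSurvival(surv)
  if (!nrow(surv)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = surv,
                           conf.type = "log-log")
  tab <- summary(fit)$table
  keep <- fit$n.event > 0
  s <- fit$surv[keep]
  tt <- fit$time[keep]
  # median by the explicit rule: earliest time the curve falls to <= 0.5
  # (survfit's table instead averages boundary times on an exact 0.5)
  med <- if (any(s <= 0.5)) tt[which(s <= 0.5)[1L]] else NA_real_
  new("KmCurve", group = group, time = tt, survival = s,
      atRisk = fit$n.risk[keep], events = fit$n.event[keep],
      greenwoodVar = (fit$std.err[keep] * s)^2,
      median = med,
      medianLower = unname(tab["0.95LCL"]),
      medianUpper = unname(tab["0.95UCL"]))
}

#' Log-rank test across groups
#'
#' Standard log-rank (Mantel-Haenszel) test comparing the survival
#' distributions of two or more groups.
#'
#' @param groups named list of survival data.frames (>= 2, all
#'   non-empty).
#' @return list with \code{chi_square}, \code{df} (= number of groups -
#'   1) and \code{p_value}.
#' @export
logrankTest <- function(groups) {
  if (length(groups) < 2L)
    stop("at least 2 groups are required", call. = FALSE)
  groups <- lapply(groups, validateSurvival)
  if (any(!vapply(groups, nrow, integer(1L))))
    stop("empty group supplied", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  pooled <- do.call(rbind, lapply(names(groups), function(g)
    cbind(groups[[g]], group = g)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = pooled)
  df <- length(groups) - 1L
  list(chi_square = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cytokine-array fold changes against a reference condition
#'
#' Densitometry post-processing of an antibody-array experiment: the
#' median background intensity is subtracted from each spot's mean
#' signal intensity, non-positive corrected intensities are clipped to
#' \code{eps} so ratios stay finite, and each condition's corrected
#' intensity is divided by the reference condition's.
#'
#' @param table data.frame with columns \code{cytokine},
#'   \code{condition}, \code{mean_signal}, \code{median_background}.
#' @param reference reference condition name; default "2D".
#' @param eps floor for corrected intensities; default 1e-6.
#' @return data.frame with columns \code{cytokine}, \code{condition},
#'   \code{corrected}, \code{fold_change} (non-reference conditions
#'   only).
#' @export
cytokineFoldChange <- function(table, reference = "2D", eps = 1e-6) {
  need <- c("cytokine", "condition", "mean_signal", "median_background")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$mean_signal < 0) || any(table$median_background < 0))
    stop("intensities must be non-negative", call. = FALSE)
  table$corrected <- pmax(table$mean_signal - table$median_background,
                          eps)
  ref <- table[table$condition == reference, ]
  if (!nrow(ref)) stop("no rows for reference condition '", reference,
                       "'", call. = FALSE)
  other <- table[table$condition != reference, ]
  miss <- setdiff(unique(other$cytokine), ref$cytokine)
  if (length(miss))
    stop("cytokine(s) missing in reference: ",
         paste(head(miss, 5L), collapse = ", "), call. = FALSE)
  other$fold_change <- other$corrected /
    ref$corrected[match(other$cytokine, ref$cytokine)]
  rownames(other) <- NULL
  other[, c("cytokine", "condition", "corrected", "fold_change")]
}
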