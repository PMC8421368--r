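---
title: "Replicate-free cell-state classification of glioma cultures: models and methods"
author: "gliomaNiche maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-free cell-state classification of glioma cultures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomaNiche)
```

# Scope

gliomaNiche classifies glioma culture conditions by cell state from
transcriptomes that come without replicates: one bulk RNA-seq profile per
condition, public single-cell atlases, spatially resolved anatomic-feature
profiles, and cohort survival tables. The package chains six pieces of
machinery: (i) log2 CPM normalisation; (ii) a replicate-free
differential-expression statistic built on ordinary-least-squares
prediction intervals; (iii) consensus gene-list compilation across
comparisons; (iv) preranked GSEA and single-sample GSEA (ssGSEA) scoring
of cells, clusters and spatial features, with meta-module labelling of
single-cell clusters; (v) anatomic niche assignment of genes; and (vi)
median-split survival stratification with Kaplan-Meier estimation. A
synthetic-data module generates every input with planted truth so the
whole pipeline is testable offline.

# Normalisation

Counts are scaled per sample to counts per million,
$\mathrm{CPM}_{gs} = 10^6 \, c_{gs} / \sum_g c_{gs}$, then transformed as
$\log_2(\mathrm{CPM} + 1)$. The pseudocount is added on the CPM scale, so
a zero count maps to exactly 0. No gene filtering is applied by default
(`cpmNormalize(min_total = )` exists but is off); readers reject missing
values rather than imputing. The resulting matrix carries a `"log2cpm"`
tag that downstream functions check, which prevents accidentally feeding
raw counts or double-transformed values into the statistics.

# The replicate-free differential-expression statistic

With a single test and a single control profile there is no dispersion to
estimate, so the method treats the gene cloud itself as the replication.
One global OLS regression of the test sample on the control sample is
fitted over all genes,
$y_g = \beta_0 + \beta_1 x_g + \varepsilon_g$, with
$x_g$ the control and $y_g$ the test $\log_2(\mathrm{CPM}+1)$ value. For
each gene the two-sided $100\gamma\%$ prediction interval for a new
observation at $x_g$ is

$$\hat y_g \pm t_{1-(1-\gamma)/2,\,n-2}\; s \sqrt{1 + \tfrac1n +
\tfrac{(x_g - \bar x)^2}{S_{xx}}},$$

with $s$ the residual standard deviation on $n-2$ degrees of freedom and
$\gamma = 0.99$ by default. A gene is called **up** iff
$y_g > \text{upper PI}$ *and* $y_g - x_g > 1$; **down** iff
$y_g < \text{lower PI}$ *and* $y_g - x_g < -1$. Both conjuncts are
required: the interval exceedance supplies the significance surrogate,
the 1-log2-unit threshold the effect-size floor. Each gene also gets a
z-score

$$z_g = \left|\frac{\hat y_g - y_g}{(\hat y_g - \text{upper PI})/2}\right|,$$

i.e. the residual in units of half the one-sided interval width. The
denominator is stored as a magnitude; when the interval collapses
(zero residual variance) the z-score is defined as 0 for a perfectly
predicted gene and `Inf` otherwise, and the infinite sentinel sorts above
every finite z in the volcano ordering. Volcano plots for these
comparisons use z on the y-axis where a replicated design would use
$-\log_{10} p$.

Assumptions worth stating: the regression is global and homoscedastic,
so the interval width is one number for the whole transcriptome (up to
leverage). Count noise is not homoscedastic on the log scale — lowly
expressed genes fluctuate more — so the global interval is mildly
conservative for well-expressed genes and mildly anti-conservative for
the low-expression tail. The calibration tests quantify this: under a
pure negative-binomial null (dispersion 0.1, 20M-read libraries) the
mean called fraction sits near 1.1%, slightly above the 1% that the
interval's nominal coverage would suggest, precisely because of that
variance heterogeneity. Users comparing very shallow libraries should
expect the excess to grow. The t quantile with $n-2$ degrees of freedom
is used throughout (the standard choice for `predict()`-style intervals);
at transcriptome-scale $n$ it is indistinguishable from the normal.

The gene universes of the two samples must match exactly; silently
intersecting them would hide upstream mistakes, so a mismatch is an
error.

# Consensus gene lists

Two rule engines compile lists from several comparisons.
`compileConsensusList()` implements the strict rule used for a
culture-condition list built from three patient lines: a gene is kept
iff it is *overexpressed* ($\Delta > 1$) in all three comparisons and the
overexpression is *significant* (the full prediction-interval up call) in
at least two. `compileSupportedList()` implements the corroboration rule
used for a stem-cell-versus-differentiated list: overexpressed in at
least two of the three primary comparisons, or in one of them plus at
least one supporting study. "Overexpressed" is deliberately the
fold-change conjunct alone, and "significant" the full call — the two
notions the calling rule distinguishes. Both engines are monotone
(adding support never removes a gene), order-invariant, and carry
per-gene provenance so membership can be re-derived. Down-regulated
lists are available through `comparisonFlags(direction = "down")` but
are not compiled by default. The engines validate their inputs
exhaustively against truth tables in the test suite; reproducing the
published list contents would require the original cohort downloads and
is out of scope.

# Enrichment scoring

`rankGenes()` converts a comparison into a preranked list with metric
$\mathrm{sign}(\Delta_g)\, z_g$ — the natural analogue of the volcano
convention, since the method yields z-scores rather than p-values. Ties
(including all-zero metrics) break lexicographically on gene id, making
the ranking deterministic.

`gseaPreranked()` computes the classic weighted Kolmogorov-Smirnov
enrichment score: walking down the ranking, in-set genes add
$|r_g|^w / \sum_{h \in S} |r_h|^w$ (weight $w = 1$ by default), out-set
genes subtract $1/(N - |S|)$, and the ES is the signed maximum deviation
of the running sum. Significance comes from gene-label permutations:
NES divides the ES by the mean |permuted ES| of the same sign, the
nominal p is the fraction of permutations at least as extreme in the
observed direction, and the FDR q compares observed and pooled permuted
NES in the standard way. Two numerical choices matter. First,
`n_perm = "all"` enumerates every $\binom{N}{|S|}$ placement, and the
nominal p is defined without a pseudo-count so that exhaustive
enumeration returns the exact fraction; mathematically tied ES values
can differ in the last float bit across placements, so ties are counted
as extreme with a $10^{-12}$ tolerance. Second, sets whose in-list size
falls outside `[min_size, max_size]` (defaults 5 and 2000) are skipped
with a warning rather than scored. If every in-set metric is zero the
hit weights fall back to equal increments.

`ssgseaScore()` implements the single-sample score as the summed
difference between the rank-weighted in-set empirical CDF and the
uniform out-set CDF, with rank weights $r^\alpha$, $\alpha = 0.25$ (the
cited method's default; the top-ranked gene carries rank $N$). Being a
pure rank statistic it is invariant under strictly monotone transforms
of the profile — CPM, TPM, or their logs give identical scores — which
is why the choice of upstream unit for public single-cell data is
immaterial. Scores are reported raw; `ssgseaScores(normalize = TRUE)`
optionally divides by the overall score range when units are compared.

Single cells are assigned to the meta-module with the maximal ssGSEA
score (`assignCellModules()`, ties unassigned). Clusters are labelled
either by the majority rule — a module must exceed 50% of the cluster's
cells, else "unassigned" — or by the max-frequency rule, which accepts a
plurality and returns "unassigned" only on a tie. Cells whose own module
is unassigned count toward cluster size but never supply the label.
`averageClusters()` provides the companion per-cluster mean profiles.

# Spatial niche assignment

For each gene, its mean log2 CPM profile across anatomic features is
z-scored across features, and the gene is assigned to the feature with
the maximal z provided that maximum exceeds 1; otherwise it stays
unassigned. Features map onto four niche groups through a fixed table:
PAN and PNZ_ccGSC are Perinecrotic, MVP and HBV_ccGSC Perivascular, LE
and IT the Tumor periphery, CT and CT_control the Tumor core. A gene
with zero variance across features is unassigned (counted in a message,
not an error). When only two features are present the z-scores are
exactly $\pm$ equal by construction, and neither can exceed 1, so no
assignment is possible — the rule needs at least a handful of features
to be meaningful.

# Survival stratification

`stratifyByScoreMedians()` dichotomises each of two signature scores at
its cohort median and crosses the dichotomies into four groups. Ties at
the median go to "low" — the deterministic choice; no convention is
universal here, and the tie rule only matters for cohorts with exactly
duplicated scores. `kmFit()` wraps the survival package's product-limit
estimator with Greenwood variance; the median is reported by the
explicit rule "earliest time at which the curve falls to ≤ 0.5" (the
survival package's table instead averages boundary times when the curve
sits exactly at 0.5 — the explicit rule is kept because it is the one
the downstream ordering checks are defined with), and its 95% CI is the
Brookmeyer-Crowley construction on the log(−log) scale, with unbounded
sides reported as `NA`. `logrankTest()` is the standard Mantel-Haenszel
comparison. Expected usage: score A is the hydrogel-culture (3D-GMH)
list, score B the stem-cell (GSC) list, and the clinically interesting
contrast is lowA_highB versus highA_lowB.

# Cytokine arrays

`cytokineFoldChange()` post-processes antibody-array densitometry:
median background is subtracted from mean spot signal, corrected
intensities are floored at $\varepsilon = 10^{-6}$ so ratios stay
finite, and each condition is divided by the reference (2D) condition.
Pixel extraction from blot images is upstream of the package.

# The synthetic-data generators

The generators exist so that every stage can be exercised against known
truth with no download; their defaults are fixed once and the tests are
run under them.

* **Bulk pairs** (`simulateCountPair()`): gene-wise baseline log2
  relative abundances are drawn from a normal with mean 4 and sd 2 (a
  broad lognormal on the abundance scale, spanning roughly 0.1–10,000
  CPM — the dynamic range of a filtered bulk matrix), scaled to a 20M
  count library (a typical HiSeq depth), with negative-binomial counts
  at dispersion 0.1. Planted log2 effects (default +3 on 50 genes,
  placed on genes with baseline CPM ≥ 100) shift the test means.
  Dispersion 0 degenerates to rounded means, giving an exactly
  noise-free pair.
* **Single cells** (`simulateSingleCells()`): clusters of cells with a
  planted meta-module each; *purity* is implemented as the exact
  fraction (rounded up) of a cluster's cells carrying the module, not a
  Bernoulli rate, so that any purity above 0.5 keeps the planted module
  in the majority by construction and the majority-rule recovery
  property is a property of the labelling rule rather than of sampling
  luck. Expression is baseline plus Gaussian noise plus an additive
  3-log2 shift on the cell's own module genes, floored at 0 to stay in
  log2(CPM+1) space.
* **Spatial profiles** (`simulateSpatialProfiles()`): constant per-gene
  baselines across the eight anatomic features, Gaussian feature noise,
  and per-feature marker genes shifted by 3 noise-sd units.
* **Survival** (`simulateSurvival()`): exponential event times per
  group with hazards defaulting to median survivals of roughly
  3500/1400/1400/600 days for lowA_highB / lowA_lowB / highA_highB /
  highA_lowB — the prognosis ordering expected when score A tracks the
  hydrogel signature; independent uniform censoring with the horizon
  solved numerically to hit the requested censoring rate (default 20%);
  and score columns drawn from disjoint low/high bands so the median
  split reproduces the planted groups exactly.

What the generators deliberately do **not** emulate: gene-gene
correlation, batch effects, mean-dependent dispersion trends, library
composition biases, zero inflation, or the covariance structure of real
single-cell data. Passing tests therefore demonstrate that the
implemented rules and statistics behave as specified under a clean
generative model — not that the biological conclusions drawn from any
real cohort would be robust.

# Problem sizes and determinism

The test suite and the acceptance script use 5000-gene pairs with 200
null replicates and 50 sensitivity replicates, 160-cell single-cell
simulations, 200-gene spatial profiles, and 200 survival cohorts of 200
patients per group — sizes at which the Monte-Carlo properties of
interest (calibration near 1%, recovery above 95%) are measured with
comfortable precision while a full run stays in the tens of seconds.
All randomised routines take explicit seeds; permutation p-values,
generator outputs and the demo report (`runDemo()`) are byte-reproducible
given the same seed.

# Known limitations

* The replicate-free statistic inherits the homoscedasticity of its
  single global regression; its null call rate is slightly above the
  nominal $1-\gamma$ under realistic count noise (see the calibration
  discussion above), and it applies no multiple-testing correction —
  by design, since the downstream consensus rules provide the
  filtering.
* NES and FDR q are permutation estimates; with the default 1000
  permutations the smallest resolvable nominal p is $10^{-3}$ (reported
  as 0 below that).
* The spatial rule assigns each gene to at most one feature; genes with
  genuinely multimodal spatial profiles are reduced to their argmax.
* `kmFit()` reports a median only when the curve actually crosses 0.5;
  heavily censored groups yield `NA` medians, which the ordering
  utilities treat as incomparable.
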