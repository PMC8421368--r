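Package: gliomaNiche
Title: Cell-State Classification of Glioma Culture Conditions from
    Replicate-Free Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying glioma culture conditions by cell state
    from bulk and single-cell transcriptomes. Implements a replicate-free
    differential-expression statistic based on ordinary-least-squares
    prediction intervals between a single test and control sample,
    consensus gene-list compilation across comparisons, preranked gene set
    enrichment analysis (GSEA) with permutation normalisation, single-sample
    GSEA (ssGSEA) signature scoring of cells, clusters and spatial features,
    glioblastoma meta-module assignment of single-cell clusters, anatomic
    niche assignment of genes from spatial feature profiles, and
    median-split survival stratification with Kaplan-Meier estimation.
    Includes a synthetic-data generator emulating the statistical structure
    of the inputs so that the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
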