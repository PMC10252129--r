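Package: txmeta
Title: Random-Effects Meta-Analysis of Multi-Study Transcriptomic Case-Control Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Integrates differential-expression results from many independent
    case-control transcriptomic studies (microarray log2 intensities and
    RNA-seq counts) by DerSimonian-Laird random-effects meta-analysis with
    significance filters and leave-one-out sensitivity analysis, runs
    hypergeometric over-representation analysis against GMT gene-set
    collections, and evaluates count-based gene-signature risk scores on
    survival cohorts with Kaplan-Meier, log-rank and Cox proportional-hazards
    methods. Includes a synthetic-data module generating multi-study
    expression compendia and expression-linked survival cohorts with known
    ground truth, plus an end-to-end pipeline with a static report export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    metafor,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
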