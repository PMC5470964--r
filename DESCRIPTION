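Package: sdtclass
Title: Expression-Based Classification of SMARCB1-Deficient Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to separate rhabdoid tumors (RT) from SMARCB1-deficient
    non-rhabdoid tumors (SD-NRT) on bulk expression profiles. Implements the
    pre-clustering gene filters (background, fold change, relative
    interquartile spread), multi-run non-negative matrix factorization with
    consensus matrices, cophenetic and PAC rank diagnostics, NMF- and Welch
    t-test-based signature extraction, silhouette-scored supervised
    classification of uncertain samples with subtype centroid calls, an
    imprinted-gene over-representation test, a somatic variant filter
    cascade with CNV summaries, 2^-ddCt qPCR quantification, clinical cohort
    outcome summaries, and a synthetic cohort generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
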