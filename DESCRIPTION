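Package: risisr
Title: Robust Binary Subtype Discovery and Validation for Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Unsupervised discovery of binary tumor subtypes from gene
    expression with bootstrap stability selection (rISIS), independent
    confirmation from microRNA profiles via nearest shrunken centroid
    classification with nested cross-validation, a portable gene-signature
    subtype score with Gaussian-mixture bimodality assessment, and
    downstream survival and clinical-association statistics. Includes a
    synthetic cohort generator emulating the data structure of a
    duplicate-bearing ovarian cancer expression study, so every stage of
    the pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    yaml,
    survival,
    limma,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
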