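Package: inforx
Title: Informative-Gene Selection and Drug-Response Modeling for
    Pharmacogenomic Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects informative gene subsets from cancer cell-line
    transcriptomes and models drug response (natural-log IC50) with
    penalized linear and kernel regression. Implements drug-unspecific
    gene selection by expression-variance ranking with correlation-based
    redundancy clustering, drug-specific gene selection by extreme-decile
    expression/IC50 correlation screening inside each training split,
    permutation split protocols with leakage-free per-split selection,
    interactome-neighborhood and pathway gene sets around known drug
    targets, and downstream analyses: drug-unique genes, per-gene
    contribution, median-split response binarization with confusion
    metrics, fingerprint and IC50-profile drug similarity, drug-class
    leave-one-out transfer, and mutation-response association. Ships a
    synthetic-cohort generator with planted causal genes so every stage
    is testable end-to-end without external screening data.
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
    glmnet,
    igraph,
    jsonlite,
    kernlab,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    fgsea,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
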