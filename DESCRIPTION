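Package: phenodose
Title: Phenotype Profiles and Dose-Reduction Prediction from Longitudinal
    Prescription Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects drug dose-change and dose-continuation intervals in
    longitudinal prescription records, builds ontology-expanded binary
    phenotype features from prior diagnoses, note-derived condition mentions
    and laboratory orders, selects enriched phenotype profiles with a
    hypergeometric filter cascade (risk ratio, information content,
    Bonferroni correction and ontology-aware 'elim' pruning), and trains
    balanced random-forest classifiers evaluated by stratified
    cross-validation with per-fold feature selection and by temporal holdout.
    Ships a seeded synthetic cohort generator with planted feature-outcome
    associations so that every pipeline stage can be validated against a
    known ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lubridate,
    pROC,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
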