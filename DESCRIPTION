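Package: roughtabu
Title: Rough-Set Attribute Reduction by Tabu Search with Classifier Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature selection for labeled feature tables via rough-set
    attribute reduction driven by Tabu search: exact dependency-degree
    calculus on discrete decision tables, a Tabu-search reducer with
    neighborhood mutation, frequency-based diversification, shaking of the
    incumbent and an elite-reduct intersection, plus quantile/width
    discretization for continuous features, seeded synthetic-data
    generators with planted reducts, and a benchmarking harness that
    compares five standard classifiers with and without the selected
    features using accuracy, precision, sensitivity, F1 and ROC AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
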