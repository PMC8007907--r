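Package: nllmda
Title: Microbe-Disease Association Prediction by Linear Neighborhood
    Label Propagation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts unobserved microbe-disease associations from a
    sparse binary association matrix with the NLLMDA framework: Gaussian
    association-profile (GAP) kernel similarities for microbes and
    diseases, symptom-based disease similarity, linear neighborhood
    similarity learned by simplex-constrained quadratic programming,
    reliable negative-pair selection by random walk with restart on the
    heterogeneous microbe-disease network, closed-form label propagation
    on each neighborhood graph, and convex integration of the per-model
    score matrices. Includes three cross-validation protocols (new
    microbes, new diseases, new pairs), ranking metrics, hyperparameter
    grid search, and a synthetic benchmark generator with planted
    cluster structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
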