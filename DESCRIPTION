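Package: polyfc
Title: Coordination and Subclass Modeling of Polyfunctional Antibody Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for humoral polyfunctionality across HIV-infected
    subject groups: group-wise coordination statistics over seven antibody
    Fc-effector assays (pairwise Spearman correlation distributions compared by
    Friedman/Dunn tests), IgG subclass landscape analysis (positivity prevalence,
    co-induction, Kruskal-Wallis/Dunn level comparisons), titer-function and
    relative-level correlation matrices, and a permutation-validated, repeatedly
    cross-validated ridge classifier predicting polyfunctional status from
    gp120-specific IgG subclass titers. Includes a Gaussian-copula / shared-factor
    synthetic cohort generator reproducing the statistical structure the analysis
    assumes, so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr,
    optparse,
    patchwork
Config/testthat/edition: 3
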