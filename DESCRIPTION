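Package: maprs
Title: Multi-Ancestry Polygenic Risk Scores via Ensembled Penalized Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds ancestry-specific polygenic risk scores (PRS) by jointly
    modelling GWAS summary statistics from multiple populations. A per-population
    lasso penalty induces sparsity while a cross-population ridge penalty on
    effect-size differences borrows strength between ancestries; the resulting
    grid of candidate PRSs is combined with a cross-validated super-learning
    ensemble into a single SNP-weight vector per target population. Includes a
    lassosum-style single-ancestry solver that supplies reference tuning
    parameters, per-block LD estimation from PLINK reference panels, a synthetic
    multi-ancestry data generator for end-to-end testing, and evaluation metrics
    (residualized R-squared, AUC, liability/logit-scale variance).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    glmnet,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
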