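Package: nlprs
Title: Nonlinear Polygenic Prediction with LASSO-Selected SNPs and
    Gradient Boosted Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and evaluates nonlinear polygenic prediction models for
    quantitative traits. Provides phenotype harmonization (outlier trimming,
    medication adjustment, covariate regression, rank-inverse-normal
    transformation), a native clump-and-threshold polygenic risk score with
    grid tuning, an ensemble that jointly cross-validates LASSO SNP selection
    with gradient boosted regression trees (optionally including the PRS as a
    feature), REML variance-component heritability, percentage-variance-
    explained evaluation with group stratification, and a multi-ancestry
    genotype and trait simulator so the whole pipeline runs end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
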