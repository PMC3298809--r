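Package: metaboforest
Title: Random-Forest Biomarker Discovery for Metabolite Feature Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Multivariate analysis pipeline that predicts long-term fasting
    plasma glucose development (delta-glucose, mg/(dl*a)) from a GC-MS
    metabolite feature table: below-limit-of-detection imputation and
    log-normalization, univariate Spearman screening with collinearity
    diagnostics, a linear regression baseline, random-forest regression
    with out-of-bag permutation importance, iterative importance-halving
    feature selection with plateau-stability stopping, and leakage-safe
    repeated tenfold cross-validation. Includes a seeded synthetic cohort
    generator with correlated lognormal metabolite blocks so the full
    pipeline is testable without access to clinical cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    randomForest,
    Rcpp,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
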