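Package: fcage
Title: Brain-Age Modelling from Resting-State Functional Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying and predicting chronological age
    from resting-state functional connectivity. Builds Fisher-z connectivity
    matrices and node-level fALFF from ROI time series, decomposes the
    cross-subject edge matrix into intrinsic and age-related principal
    components, fits mass-univariate linear and quadratic lifespan models
    with covariates and FDR control, extracts component-coefficient,
    supervised-reduced-edge and temporal features, trains OLS, lasso and
    support-vector age regressors with internal cross-validation and
    external validation, and identifies predictive edges against a
    permutation null. A synthetic-cohort generator with planted intrinsic
    and age-related structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
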