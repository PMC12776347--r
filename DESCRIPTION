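Package: cmmp
Title: Classified Mixed Model Prediction of DNA Methylation with
    Data-Driven Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Predicts denoised (true mixed-effect) DNA methylation from
    genetic and clinical covariates by clustering samples on their
    methylation profiles with k-means, fitting a linear mixed model with a
    cluster random intercept independently for each methylation outcome,
    and assigning each test observation to a training cluster by
    classified mixed model prediction (CMMP).  Includes gap-statistic
    selection of the number of clusters, Infinium-style beta-value
    preprocessing (boundary-missing handling, SD and variance filters,
    correlation pruning, M-value transform, within-cancer
    standardization), a parametric-bootstrap estimator of the mean squared
    prediction error, and a simulation framework emulating a pan-cancer
    cohort with controllable racial under-representation for validating
    CMMP against naive and regression predictors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    jsonlite,
    mclust,
    stats,
    utils,
    withr,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
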