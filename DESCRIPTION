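Package: cgfmap
Title: Model-Based Geostatistics for Mapping Child Growth Failure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Bayesian model-based geostatistics for mapping the prevalence of
    child growth failure (stunting, wasting, underweight) on a pixel grid over
    space and time. Converts child anthropometry to LMS z-scores, collapses
    microdata to cluster-level binomial observations, adjusts weight-for-height
    z-scores for within-year seasonality, resamples areal (polygon) survey
    observations to weighted pseudo-points, builds stacked-generalization
    ensemble covariates from three child learners, and fits a binomial
    spatio-temporal Gaussian process model with a Kronecker Matern-by-AR1
    covariance and an observation-level nugget via an empirical-Bayes
    state-space (Kalman filter) engine. Posterior candidate maps are
    aggregated to administrative units, raked to national prevalence series,
    projected forward by weighted annualized rates of change on the logit
    scale, and summarized as probabilities of meeting WHO Global Nutrition
    Targets. Ships a synthetic-world generator with known truth for
    end-to-end validation, a spatially stratified cross-validation harness,
    and an exact MCMC backend for small instances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mgcv,
    glmnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
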