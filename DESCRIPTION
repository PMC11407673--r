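Package: camoccu
Title: Bayesian Single-Season Occupancy Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring habitat-use drivers of elusive wildlife from
    camera-trap data: construction of detection/effort history matrices from
    raw records and deployment intervals (stacked camera-year design,
    independence filtering, fixed-length occasions), covariate standardization
    and Spearman collinearity screening, Bayesian single-season occupancy
    models with site and observation covariates and an optional random
    station intercept (JAGS backend), model ranking by Pareto-smoothed
    importance-sampling leave-one-out expected log predictive density with
    pseudo-BMA or stacking weights, MacKenzie-Bailey chi-square
    goodness-of-fit via posterior-predictive simulation, and projection of
    the fitted model onto regular grids to map habitat suitability. A
    synthetic-data generator reproduces the statistical structure of a
    montane camera-trap study so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    withr,
    stats,
    utils
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
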