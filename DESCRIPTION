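Package: ispyengine
Title: Bayesian Adaptive Platform-Trial Engine with Calendar-Drift
    Adjustment and IGF Biomarker Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Re-usable engine for neoadjuvant platform trials with a binary
    pathologic complete response endpoint: a logistic covariate model with
    HER2-stratified normal dynamic linear model ("time machine") offsets that
    let non-concurrent controls inform current comparisons, posterior
    inference by adaptive Metropolis-within-Gibbs, and the platform decision
    rules (probability an arm is superior to control, predictive probability
    of success in a hypothetical confirmatory phase 3 trial, graduation and
    futility, response-adaptive randomization). Companion modules score
    IGF-axis gene-expression signatures (ligand-correlation score and the
    signed-signature regression t-statistic score), run the 3-model
    qualifying biomarker evaluation with likelihood-ratio interaction tests,
    analyze longitudinal HbA1c glycemic control, and generate synthetic
    trial, expression, and HbA1c data with the statistical structure the
    analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    withr
Config/testthat/edition: 3
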