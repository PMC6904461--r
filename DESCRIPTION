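Package: colliderfree
Title: Collider-Robust Prognosis Prediction and Treatment-Effect
    Estimation from Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation-based toolkit for studying and removing collider
    bias in image-based prognosis models. Provides a structural causal
    model in which tumour size acts as a pre-treatment collider and
    radiodensity heterogeneity as a prognostic factor, a synthetic
    nodule-image generator with controllable size and heterogeneity, a
    feature-matching sampler that ties images to simulated patients, a
    small multi-task convolutional network whose last-layer activations
    are constrained to be linearly independent of the measured collider,
    and post-hoc ordinary-least-squares estimators of the average
    treatment effect together with regression baselines and a
    scale-mismatch sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
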