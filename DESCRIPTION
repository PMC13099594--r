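Package: cogtraj
Title: Latent-Class Trajectory Analysis of Preclinical Cognitive Decline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for growth-mixture analysis of longitudinal cognitive
    composite scores in preclinical Alzheimer's disease cohorts. Provides a
    latent-class mixed-effects model (Box-Cox outcome transformation, natural
    cubic spline time effects, subject-level random intercepts, and a
    multinomial-logistic class-membership submodel), posterior classification
    with BIC/ICL model selection, stratified cross-validated baseline
    prediction with precision-recall evaluation, classification-tree profiling
    of latent classes, class-stratified clinical-trial power analysis with
    attrition, and a calibrated synthetic-cohort generator so the full
    pipeline runs without access to restricted study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    nlme,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
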