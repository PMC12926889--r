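Package: trialcea
Title: Trial-Based Cost-Effectiveness Analysis of Depression Screening Feedback
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the health-economic evaluation of a
    three-arm cluster-structured randomised trial of feedback interventions
    after depression screening in primary care. Generates synthetic
    participant-level trial data with the structure the analysis assumes
    (practice-nested-in-centre clustering, right-skewed two-part costs,
    missing-at-random follow-up data), scores the EQ-5D-5L and PHQ-9,
    converts longitudinal scores into quality-adjusted life years and
    depression-free days, costs resource use from societal and payer
    perspectives at 2022 prices, performs multiple imputation by chained
    equations with Rubin pooling, fits linear and gamma log-link mixed
    models with practices nested in centres, and derives incremental
    cost-effectiveness ratios, net-benefit regressions and
    cost-effectiveness acceptability curves over willingness-to-pay grids,
    including deterministic sensitivity scenarios and subpopulation
    analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    lme4,
    glmmTMB,
    sandwich,
    nnet,
    MASS,
    digest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
LinkingTo: Rcpp
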