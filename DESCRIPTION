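Package: riskrecal
Title: Validation and Recalibration of Cardiovascular Mortality Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for external validation and recalibration of
    cardiovascular-disease (CVD) mortality risk prediction equations.
    Scores individual risk-factor profiles under parameter-driven model
    specifications (Framingham-type proportional-hazards equations,
    SCORE-type Weibull cause-specific equations, the Chinese ischemic CVD
    model and the Pooled Cohort Equations), assesses discrimination
    (ROC/AUC with DeLong confidence intervals, sensitivity/specificity and
    likelihood ratios at recommended and Youden-optimal cut-offs) and
    calibration (Kaplan-Meier adjusted observed versus predicted events by
    risk decile with small-group collapsing, Greenwood-Nam-D'Agostino
    chi-square test), recalibrates model parameters to a target cohort
    (mean/baseline-survival replacement or full coefficient refit), and
    generates synthetic cohorts with known outcome models for end-to-end
    testing and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    survival,
    pROC,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
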