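Package: amyloidrisk
Title: Plasma Abeta42/Abeta40 Risk Modelling for CSF Amyloid Positivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fits and validates a logistic risk model that predicts cerebrospinal
    fluid (CSF) amyloid positivity in mild cognitive impairment from the plasma
    Abeta42/Abeta40 ratio, age and APOE epsilon-4 carriage. Provides the full
    evaluation pipeline for dual-cutoff ("grey zone") decision rules: ROC/AUC with
    DeLong confidence intervals, Youden threshold selection, predictive-value
    curves and cutoff pairs at fixed PPV/NPV targets, prevalence-fixed bootstrap
    resampling, Monte Carlo measurement-noise robustness studies, logistic
    recalibration with flexible LOESS calibration curves, Deming regression and
    rank-correlation agreement statistics, and a synthetic two-cohort generator
    that emulates the joint structure of real memory-clinic populations so every
    stage is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
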