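Package: epwscreen
Title: Fetal Growth Standards and Percentile-Weight Screening for
    Small-for-Gestational-Age Birth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare fetal growth standards for third-trimester
    screening of late-onset small-for-gestational-age (SGA) birth and
    adverse perinatal outcomes.  Implements estimated fetal weight (EFW)
    formulas from ultrasound biometry, estimated percentile weight (EPW)
    engines for non-customized z-score curves, Gardosi-style customized
    standards, and quantile-grid standards, SGA classification against a
    birthweight reference, and a screening evaluation battery: DeLong
    AUC with paired tests, sensitivity and threshold percentiles at
    fixed false-positive rates, two-proportion tests, logistic odds
    ratios per percentile point, and ultrasound-delivery interval
    stratification.  A synthetic cohort generator with a Gaussian-copula
    percentile-persistence model makes the full pipeline testable
    without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
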