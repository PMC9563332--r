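Package: fbctrend
Title: Dynamic Colorectal Cancer Risk Prediction from Full Blood Count Trends
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sex-stratified dynamic prediction of two-year colorectal cancer
    risk from five-year trends in routinely collected full blood count (FBC)
    measurements: haemoglobin, mean corpuscular volume and platelet count.
    Implements a two-stage multivariate joint model in which per-analyte
    linear mixed-effects sub-models (linear splines in age and time, random
    intercept and slope per patient) supply best linear unbiased predictions
    of each patient's deviation from the average population trend, and a Cox
    proportional-hazards sub-model (fractional-polynomial age plus the three
    trend deviations, Breslow baseline survival at two years with mean-centred
    predictors) converts them to absolute risk. Includes cohort-construction
    rules for electronic health-record laboratory data (plausible-range
    filtering, a pre-outcome exclusion window, baseline anchoring of the
    five-year longitudinal clock), a validation metric suite (IPCW Brier
    score, Harrell's c, Royston-Sauerbrei D and pseudo R-squared, calibration
    slope, vigintile Kaplan-Meier calibration), percentile-threshold
    diagnostic accuracy analysis, and a synthetic EHR cohort generator for
    which the joint model itself is the generative truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
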