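Package: nhpred
Title: Nocturnal Hypoglycemia Prediction from CGM and Activity Tracker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for predicting nocturnal hypoglycemia in
    adults with type 1 diabetes on multiple daily injections, from free-living
    continuous glucose monitoring (CGM) and wrist-worn activity tracker data.
    Provides gap imputation and 5-minute resampling of CGM streams, insulin /
    carbohydrate / activity on-board physiological effect signals, hand-crafted
    pre-sleep feature extraction, per-night hypoglycemia labeling, per-patient
    classifier selection by exhaustive feature-group search under repeated
    stratified k-fold cross-validation scored by the geometric mean of
    sensitivity and specificity, CGM glucometrics reporting, and a synthetic
    free-living data generator with controllable nocturnal hypoglycemia
    prevalence.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    jsonlite,
    lubridate,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
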