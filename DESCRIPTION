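Package: gazeappraisal
Title: Eye-Tracking Features and Linear Models for Reading Appraisals
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reading-study analysis pipeline from raw 60 Hz binocular gaze
    samples to subjective appraisals of comprehensibility and interest.
    Implements dispersion-based (I-DT) fixation detection, saccade and
    regression classification with blink exclusion, Coefficient K
    (focal vs ambient attention), pupillometry features, per-session
    aggregation with statistical moments, lenient interquartile-range
    outlier removal, area-of-interest filtering, participant and block
    median-baseline normalization, dataset screening (missing values,
    near-zero variance, correlated-feature de-duplication), stepwise
    linear models with leave-one-out cross-validation, and a synthetic
    reading-gaze generator that emulates a 30-participant, 18-article
    within-subjects study for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    caret,
    e1071
Config/testthat/edition: 3
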