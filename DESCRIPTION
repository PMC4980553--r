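Package: emavalid
Title: Validation of Momentary Dietary and Activity Self-Reports Against
    Recall and Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for validating mobile ecological momentary assessment
    (mEMA) reports of eating and physical activity against 24-hour dietary
    recall and accelerometer data. Implements day-level and time-window
    match rates for food-group endorsements, window-width sensitivity and
    specificity curves, Freedson cut-point intensity classification of
    60-second accelerometer epochs, 4x4 reported-versus-derived agreement
    statistics (match rate, sensitivity, specificity, likelihood ratios,
    mixed-model odds ratios), Kolmogorov-Smirnov comparisons of count
    distributions, and mixed linear models of log-transformed counts.
    Includes a synthetic cohort generator emulating interval-contingent
    prompt schedules, recall omission and time-displacement noise, and
    intensity-dependent epoch count distributions, so the full pipeline is
    testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
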