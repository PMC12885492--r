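Package: oximcal
Title: Empirical Calibration of Dual-Wavelength Optical Blood Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibration and validation toolkit for clamp-on optical
    transmission sensors that estimate total hemoglobin concentration (Hgb)
    and whole-blood oxygen saturation (SO2) on blood-filled tubing, as used
    in extracorporeal circuits. Implements pulse-number normalization and
    cross-sensor intensity scaling, a nine-term log-intensity polynomial
    feature library fitted by cross-validated elastic net regression for
    Hgb, a concentration-corrected ratiometric linear model for SO2, and
    the full agreement-statistics suite (accuracy RMS error, mean absolute
    difference, R-squared, adjusted R-squared, Bland-Altman bias and limits
    of agreement, per-day summaries). A seeded modified Beer-Lambert
    forward model emulates an in-vitro recirculating blood-loop experiment
    for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
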