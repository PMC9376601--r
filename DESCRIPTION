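Package: tremorsense
Title: Tremor Quantification from Smartphone and Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies postural tremor from six-channel inertial recordings
    (3-axis linear acceleration, 3-axis angular velocity) such as those
    produced by a smartphone or a finger-mounted IMU. Rhythmic tremor content
    is separated from the 1/f-like fractal background of postural motion with
    the irregular-resampling auto-spectral analysis (IRASA) method on
    50%-overlapping 8-s windows; a per-window tremor index is the
    band-limited (3.5-10 Hz) maximum of the Gaussian-smoothed
    oscillatory-to-fractal ratio spectrum, and a per-recording score is the
    median of the top third of window indices pooled across time and
    channels, optionally expressed in decibels relative to a control-cohort
    mean. Includes a synthetic recording and cohort simulator, cohort
    evaluation tools (ROC/AUC, severity correlation, spectral
    peak-over-background), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
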