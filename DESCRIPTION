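Package: faaloop
Title: Closed-Loop Neuroadaptive Exposure Control from EEG Frontal Alpha
    Asymmetry and Heart Rate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating neuroadaptive virtual-reality
    exposure sessions driven by physiological fear markers. Implements the full
    computation stack: synchronized EEG/heart-rate session I/O with a documented
    delimited-text format, a Butterworth/common-average-reference/baseline
    preprocessing chain with robust bad-channel handling, Welch band-power and
    frontal-alpha-asymmetry (FAA) feature extraction, calibration of an
    individualized support-vector fear-state classifier exposing a signed
    decision distance, a five-level stimulus controller that adapts exposure
    intensity from windowed decision distances, a virtual-participant simulator
    with fear-dependent right-frontal alpha suppression and heart-rate
    arousal/habituation/bradycardia dynamics, and offline analyses (epoch
    rejection, nested cross-validated low-vs-high fear classification, feature
    importance, band topographies, level statistics, and Benjamini-Hochberg
    corrected correlation matrices).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    e1071,
    jsonlite,
    pracma,
    ranger,
    signal,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
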