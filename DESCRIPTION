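Package: iflscan
Title: Detection of Inspiratory Flow Limitation from Nasal Airflow Waveforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Breath-by-breath detection of inspiratory flow limitation (IFL)
    from single-channel nasal-cannula airflow recordings. Inspirations are
    segmented at zero crossings, normalized to a 100-point unit-square
    representation, and scored with five shape features: a flatness index
    over the middle half of the breath and the absolute-residual sums of
    first- to third-order and endpoint/peak-weighted third-order polynomial
    fits. Breaths are classified as non-flow-limited, mildly, or severely
    flow limited using shipped or ROC-recalibrated cut-offs, and classifier
    performance is summarised with per-class accuracy, sensitivity,
    specificity and a six-arm cobweb misclassification plot. A labelled
    synthetic breath generator emulating rounded, flattened and multi-peak
    inspiratory shapes supports calibration and end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    signal,
    optparse,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
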