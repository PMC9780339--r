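Package: earbeat
Title: In-Ear Infrasonic Hemodynography Signal Processing and Rhythm Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cardiovascular monitoring from in-ear infrasonic
    hemodynography (IH): an occluded-ear-canal acoustic model, a synthetic
    cardiac-acoustic signal simulator with ground-truth beat labels, a
    five-level processing pipeline (calibration, windowed quality assessment,
    adaptive-threshold beat detection, two-channel merging, vital signs
    including respiratory rate), beat stacking and lagged-correlation waveform
    fidelity, a tachogram-based atrial fibrillation / sinus rhythm random
    forest classifier with 17 heart-rate-variability features, and the
    method-agreement statistics (Pearson correlation, Bland-Altman limits of
    agreement and sample-size planning, one-way ANOVA, paired t test, Wilson
    score intervals) used to validate acoustic beat series against ECG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nnet,
    ranger,
    e1071,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
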