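Package: biostress
Title: Multimodal Physiological Characterization and Stressor Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting transient emotional stressors from
    multimodal wearable biosignals: a deterministic synthetic cohort
    simulator (electrodermal activity, inter-beat intervals, six-channel
    EEG, blink strength, self-report lever and joystick traces with
    per-channel response delays and habituation), time-scale-organized
    physiological characterizations (blink counts, tonic skin conductance
    level, Welch LF/HF heart-rate-variability ratio, square-wave encoding
    of significant slope increases, median RRI, frontal alpha asymmetry),
    Box-Cox/Spearman correlation mapping with lag estimation, EEG
    time-frequency band variance counting, and ten-fold cross-validated
    stressor-presence classification (LDA, linear SVM, logistic
    regression) from alpha band-power ratio features.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    signal,
    MASS,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
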