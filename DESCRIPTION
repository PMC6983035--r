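Package: scdemd
Title: Sudden Cardiac Death Prediction from Raw ECG via Empirical Mode
    Decomposition and Nonlinear Indices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for predicting sudden cardiac death (SCD)
    episodes from single-lead electrocardiogram recordings. One-minute ECG
    windows are decomposed by empirical mode decomposition (EMD) into
    intrinsic mode functions; five nonlinear indices (Katz, Higuchi and
    box-counting fractal dimensions, Shannon entropy, permutation entropy)
    are computed per mode; one-way ANOVA screens the resulting 30 features;
    and a multilayer perceptron trained with a Levenberg-Marquardt optimizer
    and bounding-box training augmentation classifies windows as normal or
    pre-SCD. Includes readers and writers for WFDB-dialect and CSV ECG
    records, polyphase resampling, pre-onset windowing, and a seeded
    synthetic ECG generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
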