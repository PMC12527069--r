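Package: ecgwolf
Title: ECG Heartbeat Classification with Wavelet Denoising and a
    Grey-Wolf-Tuned Hybrid Convolutional-Recurrent Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for five-class (AAMI) heartbeat classification from
    single-lead ECG: a synthetic annotated-ECG generator, WFDB-compatible
    record input/output and AAMI symbol consolidation, an R-peak-anchored
    preprocessing pipeline (segmentation, z-score normalization,
    probabilistic majority-class subsampling, discrete wavelet transform
    denoising with the universal hard threshold), from-scratch 1D
    convolutional, stacked LSTM and hybrid convolutional-recurrent
    classifiers trained with weighted cross-entropy, a Grey Wolf Optimizer
    for hyperparameter search, and confusion-matrix based evaluation
    reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
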