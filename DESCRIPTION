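Package: ecglstm
Title: LSTM Arrhythmia Classification for Imbalanced ECG Beat Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for heartbeat-level arrhythmia
    classification on heavily imbalanced ECG data. Reads WFDB-format
    records and beat annotations, denoises signals with a Daubechies-6
    discrete wavelet transform, segments 250-sample beats centered on
    annotated R-peaks, and Z-score normalizes them. Classification uses
    a long short-term memory (LSTM) recurrent network with peephole-style
    gate inputs, trained by full backpropagation through time with the
    focal loss so that abundant, easily classified normal beats do not
    dominate training, and optimized with Nadam. Includes imbalance-aware
    evaluation (one-vs-rest confusion-matrix metrics, support-weighted
    summaries, precision-recall curves with average precision) and a
    seeded synthetic beat generator so the whole pipeline is testable
    without any ECG download.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
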