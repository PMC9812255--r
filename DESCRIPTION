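Package: stgcneeg
Title: Spatial-Temporal Graph Convolutional Networks for EEG
    Functional-Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classify two-group multichannel EEG with a spatial-temporal
    graph convolutional network whose graph input is a per-window
    functional-connectivity adjacency matrix. Provides the full pipeline:
    bipolar montage derivation, Butterworth band filtering, decimation and
    segmentation into short windows; six pairwise connectivity estimators
    (Pearson correlation, magnitude squared coherence, imaginary part of
    coherency, wavelet coherence, phase locking value, phase lag index);
    spectral graph-convolution operators (normalized Laplacian, Chebyshev
    filters, renormalized first-order propagation); the ST-GCN classifier
    and a temporal-CNN baseline trained with Adam on binary cross-entropy;
    a coupled-oscillator synthetic EEG cohort generator with controllable
    group-specific coupling topology; and post-hoc analytics (accuracy
    grids, group-averaged adjacency, threshold screening of channel pairs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
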