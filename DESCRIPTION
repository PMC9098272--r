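Package: midecoder
Title: Attention-Based Depthwise-Separable ConvLSTM Decoding of Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes multiclass motor-imagery EEG with a compact deep network:
    sliding-window cropped training with trial-level prediction averaging, a
    four-block depthwise-separable convolutional feature extractor, a modified
    bidirectional ConvLSTM whose candidate path is convolutional over globally
    pooled features, and temporal attention pooling. Forward and backward
    passes are implemented natively (vectorized R plus a small C++ kernel for
    the temporal convolution) and trained with Adam under a 4-fold
    cross-validation protocol. Includes a class-conditioned ERD/ERS synthetic
    EEG generator, Welch band-power validation utilities, EDF ingestion with
    cue-relative epoching, and tidy accessors with ggplot2 diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    tibble,
    dplyr,
    tidyr,
    purrr,
    generics,
    ggplot2
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
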