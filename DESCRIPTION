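Package: stsaEEG
Title: Parallel Spatial-Temporal Self-Attention CNN for Motor-Imagery EEG Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Four-class motor-imagery EEG classification with a parallel
    spatial-temporal self-attention convolutional network. Provides causal
    exponential moving standardization, band-pass filtering and cue-aligned
    epoching of continuous multi-channel recordings; channel-wise and
    time-step-wise self-attention feature modules with learnable residual
    weights; a shallow convolutional square/log classification head; two-phase
    early-stopping training with Adam, 10-fold cross-validation and
    inter-subject transfer protocols; and a synthetic ERD/ERS generator that
    emulates class-dependent mu- and beta-band power modulation so the whole
    stack can be exercised end to end without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    tools,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
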