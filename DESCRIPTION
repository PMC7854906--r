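Package: tdann
Title: Two-Level Domain Adaptation Networks for EEG Emotion Decoding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-day and cross-subject transfer pipeline for EEG-based
    emotion recognition. Windows continuous multichannel EEG, extracts
    per-band differential-entropy features, renders them into
    topology-preserving scalp images (azimuthal equidistant electrode
    projection plus Clough-Tocher interpolation), and trains a compact
    convolutional feature generator whose representation is aligned across
    recording days or subjects by a two-level objective: multi-kernel
    maximum mean discrepancy plus adaptive batch normalization at the
    first level, and an adversarial domain discriminator with a gradient
    penalty at the second. Includes a synthetic band-structured EEG
    generator so the whole pipeline is testable without access-restricted
    recordings, and a leave-one-domain-out evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
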