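Package: gliadbn
Title: Glia-Chain Deep Belief Networks for Multichannel EEG Emotion Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ensemble deep-learning framework for recognising binary
    arousal and valence states from multichannel EEG. Implements restricted
    Boltzmann machines (RBMs) whose pretraining is modulated by a chain of
    artificial glia cells, greedy layer-wise deep belief network (DBN)
    pretraining with supervised fine-tuning, and feature-level fusion of five
    parallel glia-chain DBNs by a discriminative RBM. Ships a multi-domain
    EEG feature pipeline (time statistics, Welch band power, hemispheric
    power asymmetries, and Hilbert-Huang spectrum features), a synthetic
    labelled-EEG generator with band-limited oscillators, 1/f noise and
    interchannel mixing, and a participant-specific k-fold evaluation
    harness reporting accuracy and F1.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
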