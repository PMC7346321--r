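Package: emrisk
Title: Risk-Factor Extraction and Cardiovascular Disease Prediction from
    Clinical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A two-stage system for predicting cardiovascular disease (CVD)
    from free-text electronic medical records (EMRs). Stage one is a
    character-level BiLSTM-CRF sequence labeler that extracts mentions of
    twelve CVD risk factors together with temporal attributes (Continue,
    During, After, Before, None) under a BIO tagging scheme, with exact
    linear-chain CRF inference (forward algorithm and Viterbi decoding).
    Stage two is a deep pyramid character-level convolutional classifier
    built from a text region embedding, pre-activation residual convolution
    blocks with identity shortcuts, and size-3 stride-2 max-pool
    downsampling with a fixed number of feature maps, ending in a global
    max-pool and a binary decision head. The package also provides skip-gram
    character-embedding training with risk-factor dictionary injection,
    analytic computation-cost and receptive-field accounting for the
    downsampled network, entity-level and classification metrics, and a
    seeded synthetic-EMR generator so the whole pipeline is trainable and
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
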