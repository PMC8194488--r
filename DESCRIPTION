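Package: resemote
Title: Speech Emotion Recognition with Residual Convolutional and Recurrent
    Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes categorical emotions from short speech clips using a
    residual convolutional network over three-channel log-Mel spectrograms
    (static, delta, and delta-delta), a bidirectional LSTM sequence encoder,
    attention pooling, and a softmax classifier, trained end to end with
    cross-entropy.  Ships a speaker-independent cross-validation harness with
    unweighted average recall (UAR) and confusion-matrix reporting, ablation
    experiments over residual-block depth and feature-channel subsets, a
    deterministic synthetic-audio generator for download-free testing, a
    Berlin Emotional Database (Emo-DB) filename adapter, and a downstream
    expert-annotation aggregation and group-by-emotion contingency analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
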