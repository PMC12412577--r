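Package: whiskdecode
Title: Cross-Subject Decoding of Whisker Motion from Peripheral Nerve
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how whisker movement can be decoded from
    extraneural multi-unit recordings across animals. Provides a seeded
    generator of multi-subject cohorts (paired neural, EMG and whisker
    trajectory channels with subject-specific gain, noise floor and
    signal-to-motor latency), sliding-window signal-quality statistics
    (RMS, peak-to-peak voltage, SNR, persistence spectrum, in-band power
    ratio, envelope correlation), an encoder-attention-decoder sequence
    regression model trained with a concordance correlation coefficient
    loss, a parameter-sharing training strategy with frozen-encoder
    per-subject decoder adaptation, and a leave-one-subject-out
    evaluation protocol with adaptation-data learning curves.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    data.table
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
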