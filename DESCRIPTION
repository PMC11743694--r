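Package: earerp
Title: Attention-Modulated Auditory ERP Analysis for Scalp and Ear EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of a late positive event-related
    potential (P3b-like) component evoked by semantic target words in
    attended speech streams, recorded with scalp and in-ear EEG. Provides
    a paradigm-structured synthetic EEG generator (oddball word sequences,
    1/f background noise, ocular artifacts, scalp and ear leadfields), a
    preprocessing chain (average re-referencing, zero-phase FIR bandpass,
    ICA-based ocular artifact removal, epoching, baseline correction,
    peak-to-peak rejection), ERP averaging and peak quantification, a
    max-SNR ear-EEG spatial filter solved as a generalized eigenvalue
    problem with cross-task validation, and nonparametric permutation,
    cluster-permutation and cosine-similarity tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
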