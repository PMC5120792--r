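Package: emasynth
Title: Articulatory Speech Synthesis from Electromagnetic Articulography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for building and evaluating a real-time articulatory
    speech synthesizer driven by electromagnetic articulography (EMA).
    Implements mel-cepstral analysis and the Mel Log Spectrum Approximation
    (MLSA) vocoder with pitch-driven and fixed-template excitation, EMA
    preprocessing (head-movement correction, down-sampling, midsagittal
    projection, PCA reduction, context stacking), a layer-wise trained
    feed-forward network mapping articulatory features to mel-cepstra,
    linear cross-speaker calibration with delay estimation, a causal
    streaming synthesis pipeline, a synthetic articulatory-acoustic corpus
    generator, and intelligibility metrics (confusion matrices with
    seriation, word accuracy, mel-cepstral distortion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
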