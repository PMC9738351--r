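Package: emdnet
Title: Empirical Mode Decomposition and Convolutional Neural Network
    Classification of Interictal EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for three-way classification of interictal scalp EEG
    (epileptic seizures, psychogenic non-epileptic seizures, controls).
    Multichannel recordings in the 19-channel 10-20 montage are resampled to
    256 Hz, band-pass filtered to 0.5-32 Hz and cut into 5-second epochs with
    50% overlap; each channel of each epoch is decomposed by empirical mode
    decomposition (cubic-spline sifting) into three intrinsic mode functions,
    and the resulting 19 x 1280 x 3 tensors are classified by a compact
    convolutional neural network trained with Adam. Includes an EDF reader, a
    seeded synthetic-EEG generator with controllable class separability,
    stratified k-fold cross-validation at segment or subject granularity, and
    micro/macro classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
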