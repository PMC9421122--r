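Package: pcgaug
Title: Data Augmentation Benchmarking for Spectral-Image Heart Sound
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for comparing data augmentation
    strategies in phonocardiogram (PCG) classification from Mel-spectrogram
    images. Provides a physiologically structured synthetic heart-sound
    generator (S1/S2 transients, systolic and diastolic murmurs, S3/S4
    gallops, configurable class imbalance), Butterworth band-pass
    preprocessing with length and amplitude policies, Mel-spectrogram
    computation and fixed-size colour-image rendering, nine audio- and
    image-level augmentation operators (pitch shift, time stretch, additive
    white Gaussian noise at 0 dB SNR, horizontal and vertical flips,
    saturation/value perturbation, PCA colour augmentation, random colour
    filters, time/frequency masking, and composed variants), a fixed small
    convolutional neural network trained with Adam, and a stratified k-fold
    evaluation harness with ROC/PR curves, specificity at fixed sensitivity,
    and paired mean-difference confidence intervals against the un-augmented
    baseline arm.
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
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    png,
    pROC,
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
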