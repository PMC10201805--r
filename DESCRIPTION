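Package: eegseize
Title: Seizure Detection from Single-Channel EEG via Wavelet Subband
    Entropy Features, Random-Forest Selection and a Compact 1-D CNN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated pipeline for classifying epileptic states from
    single-channel EEG segments. Segments are band-pass filtered and
    wavelet-denoised, decomposed into five dyadic subbands (D1-D4, A4) by a
    4-level db4 discrete wavelet transform, and summarised by 20 features
    (standard deviation, approximate entropy, sample entropy and fuzzy
    entropy per subband). Features are ranked by random-forest out-of-bag
    permutation importance with recursive elimination down to 10 survivors,
    and classified by a compact one-dimensional convolutional neural
    network trained with Adam. Includes readers for Bonn-style ASCII and
    MAT-file EEG segments, a deterministic synthetic-EEG generator for
    end-to-end verification without external downloads, and confusion-matrix
    evaluation with repeated stratified 3:1 splits.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
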