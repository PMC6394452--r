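Package: erpdecode
Title: Sliding-Window Multivariate Decoding of Event-Related EEG Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate pattern classification and regression for epoched,
    preprocessed EEG. Trains linear support vector machines (or support vector
    regression) on spatial, temporal or spatiotemporal amplitude patterns in a
    sliding analysis time window, with m-times-repeated k-fold cross-validation,
    permuted-label empirical chance distributions, Haufe-corrected feature
    weights, and group-level inference (Student and Yuen paired tests,
    Holm/FDR/permutation-based multiple-comparison corrections, and
    minimum-statistic prevalence bounds). Includes a synthetic-data generator
    with known ground truth and a small command-line interface.
License: MIT
Encoding: UTF-8
Imports: Rcpp, jsonlite, stats, graphics, grDevices, utils, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
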