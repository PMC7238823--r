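Package: cnnel
Title: Slice-Wise Convolutional Ensembles for Early Detection of
    Alzheimer's Disease from Structural MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains one small convolutional network per 2D slice position of
    MNI-space T1-weighted brain volumes (sagittal, coronal and transverse
    slice families), selects the best-generalizing per-axis classifiers on a
    held-out validation cohort, and combines them by hierarchical majority
    voting into a three-axis ensemble for binary diagnosis (e.g. Alzheimer's
    disease versus healthy cognition, or conversion versus non-conversion in
    mild cognitive impairment). The MNI coordinates of the selected slices
    define intersection points whose atlas labels, accumulated over repeated
    stratified cross-validation, rank brain regions by their discriminative
    contribution. Includes class-balancing slice augmentation, repeated
    stratified cross-validation with leakage guards, performance metrics
    (accuracy, AUC, Matthews correlation), and a synthetic-cohort generator
    so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
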