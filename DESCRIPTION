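Package: mccdetect
Title: Microcalcification Cluster Detection in Digital Mammograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automated computer-aided detection (CADe) pipeline for
    clustered microcalcifications (MCCs) in digital mammograms. The pipeline
    applies an inverted logarithmic transform and breast-region masking, builds
    an 18-image filter bank (top-hat, two-level Daubechies-4 wavelet high-pass
    reconstruction, and 15 Laws texture-energy filters), detects
    microcalcification candidates by count-controlled iterative thresholding
    with dual Sobel/Canny edge detection, removes noise with knowledge-based
    size, shape and isolation rules, extracts 56 gray-level co-occurrence
    matrix texture features per candidate from each feature image, selects
    discriminative feature subsets automatically (sequential forward/backward
    selection and F-score ranking under cross-validated error), trains an
    ensemble of 18 radial-basis-function support vector machines combined by
    vote thresholding, and evaluates detections against ground truth with
    free-response ROC analysis under Kallergi's cluster-scoring criteria.
    A seeded synthetic mammogram generator provides phantoms with known ground
    truth so the complete pipeline can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
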