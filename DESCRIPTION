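Package: ctcdf
Title: Label-Free Detection of Circulating Tumor Cells in Darkfield Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable pipeline for detecting circulating tumor cells (CTCs) in
    darkfield microscopy images of unstained blood. Implements windowed
    histogram-mode illumination correction, a 15-channel multi-resolution
    feature stack (CIE L*u*v* color, gradient magnitude and quantized gradient
    orientation at three scales), discrete AdaBoost pixel classification with
    decision stumps, morphological and area-based object validation, and
    object-level evaluation against fluorescence-derived ground-truth masks.
    Includes a synthetic darkfield scene generator with paired ground truth so
    the full train/detect/evaluate loop is reproducible without microscope
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
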