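Package: clearcount
Title: Cell Detection and Regional Quantification for Cleared Whole-Brain
    Light-Sheet Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of 3D fluorescence volumes from cleared
    (CLARITY-style) mouse brains imaged by light-sheet microscopy: division
    normalization of autofluorescence background (Gaussian background model),
    Gaussian denoising, Laplacian-of-Gaussian blob detection with connected
    component extraction, gyration-tensor morphology features, random-forest
    discrimination of cells from vessel-like structures, 25 um density maps
    with atlas-driven regional cell-volume statistics, and boundary-tolerant
    validation against annotated masks. Includes a parametric synthetic-scene
    generator with exact ground truth so the whole chain is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
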