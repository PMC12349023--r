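Package: algaecount
Title: Automated Microalgae Cell Concentration Estimation from Hemocytometer Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates microalgae cell concentrations (cells/mL) from microscope
    images of a hemocytometer counting chamber. Calibrates the pixel-to-millimetre
    conversion factor from operator-cropped etalon grid squares and derives the
    suspension volume covered by one full image; detects near-spherical cells
    (e.g. Chlorella vulgaris) with a classical pipeline of green-channel CLAHE,
    luminance grayscale, median denoising and a gradient-voting Hough circle
    transform; converts per-image counts to cells/mL with dilution handling and
    per-sample aggregation; computes validation metrics (count MAE, mask IoU,
    cell-area error, percentage difference, Pearson correlation, clumping-trend
    regression); and generates synthetic hemocytometer scenes with exact ground
    truth so the whole system is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
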