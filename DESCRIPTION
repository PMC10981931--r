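Package: peridermR
Title: Segmentation and Length Measurement of Root Periderm in
    Whole-Slide Fluorescence Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A high-throughput pipeline for quantifying periderm (phellem)
    extent in Fluorol-Yellow-stained Arabidopsis thaliana roots imaged as
    stitched whole-slide fluorescence micrographs. Slides are tiled into
    fixed-size patches, segmented into background, periderm, endodermis and
    lateral-root classes by a compact nested-skip (UNet++-style)
    convolutional network with a residual encoder trained with a summed
    cross-entropy and soft-Dice loss, stitched back to slide scale, and
    cleaned by centerline-based gap bridging and hole closing. Per-root
    periderm and whole-root lengths are measured along the skeleton
    centerline and reported in pixels and micrometers. Includes pixel-level
    benchmarking (precision, recall, F1), a quality-control stage around the
    periderm-to-endodermis transition, and a synthetic slide generator with
    exact ground truth for training and testing without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    png,
    tiff,
    jsonlite,
    yaml,
    igraph
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
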