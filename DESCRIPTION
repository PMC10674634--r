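Package: kelpyield
Title: Stereo-Vision Yield Estimation for Vertical Seaweed Farms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates the surface area (m^2) of vertically hanging sugar kelp
    (Saccharina latissima) sheets from underwater frame sets consisting of an
    RGB image and a rectified grayscale stereo pair. Provides a pinhole stereo
    camera model with triangulation, a semi-global block-matching disparity
    engine with central-crop median range reduction, binary segmentation
    utilities (polygon rasterization, IoU scoring, a classical color-index
    segmenter and a pluggable external-model hook), a ground-truthed synthetic
    underwater scene generator (flat hanging sheets, turbidity haze, sensor
    noise), and a per-frame yield pipeline with repeatability statistics and a
    first-order error budget.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    xml2,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
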