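Package: rootraster
Title: Synthetic Root Images, Segmentation and Skeleton Measurement for
    Paper-Based Root Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for quantifying root system architecture from 2-D images
    of roots grown on germination paper. Generates vectorized root systems and
    renders "artificial root" images with exactly known length (spline
    centerlines, Gaussian cross-sections matched to the local diameter by full
    width at half maximum); implements the polarized two-flash preprocessing
    workflow (flat-field illumination correction, minimum-tonal fusion,
    red-channel extraction); segments roots by global, adaptive and
    double-adaptive thresholding; measures skeletonized masks (chain-code
    length, distance-transform diameters, diameter-class length distributions,
    surface and volume); analyses spectral reflectance contrast to select the
    camera channel; and scores measurement accuracy and repeatability against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    png,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    xml2
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
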