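Package: ricesar
Title: Multi-Season Paddy Rice Mapping from SAR and Optical Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A phenology-driven pipeline for mapping early, middle and late
    paddy rice from co-registered time series of C-band SAR (VH) backscatter
    and optical red/near-infrared reflectance. SAR grids are converted to
    decibels, despeckled and resampled; per rice type a three-band enhanced
    image (minimum backscatter over the early growth stage, maximum over the
    middle growth stage, and their difference) is composited from phenology
    calendar windows; a seasonal NDVI contrast image separates cropland from
    evergreen forest; K-Means clustering with cluster-to-class merging yields
    binary layers that a priority decision tree fuses into categorical maps;
    and a design-based accuracy assessment produces error-matrix-adjusted
    area estimates with standard errors, confidence intervals, user's,
    producer's and overall accuracy, and the kappa coefficient. A synthetic
    scene generator reproduces the temporal class signatures so the whole
    pipeline is testable without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
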