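Package: aggscan
Title: Segmentation and Size Statistics for Bacterial Aggregates in 3D
    Fluorescence Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies liquid-phase bacterial aggregates in single-channel
    confocal z-stacks. Provides intensity-threshold segmentation of each
    optical section, convexity-based bisection of under-segmented touching
    aggregates (shortest chord across opposite quadrants of a merged
    object), reconstruction of 3D aggregates by linking overlapping 2D
    regions across planes, physical-unit size filtering, and the derived
    statistics: aggregate volume fraction, volume-weighted mean aggregate
    volume and cross-sectional area, replicate summaries, and pooled
    two-sample Kolmogorov-Smirnov comparisons. A seeded synthetic-scene
    generator renders ground-truth stacks (ellipsoidal aggregates,
    planktonic cells, blur, depth attenuation, noise, touching pairs) for
    validation, and a tile-scan module assembles and quantifies whole-well
    mosaics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    withr,
    stats,
    grDevices,
    graphics,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    igraph,
    optparse
Config/testthat/edition: 3
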