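Package: astromorph
Title: Astrocyte Process Morphometry, Sholl Analysis and Behavioral
    Emotionality Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reproducible pipeline for quantifying astrocyte process
    morphology from GFAP immunofluorescence z-stacks and relating it to
    behavioral emotionality. Implements the ImageJ-style image chain
    (maximum-intensity projection, 8-bit conversion, thresholding,
    despeckling), topology-preserving skeletonization with
    branch/endpoint/length measurement, convex-hull shape descriptors,
    classical Sholl intersection profiles with distal-window sums, the
    four-test behavioral battery (sucrose preference, social interaction,
    elevated plus maze, forced swim) with directional Z-score
    standardization against a control group, group statistics (one- and
    two-way ANOVA with Tukey comparisons) and morphology-behavior
    correlation. A synthetic-data module generates branching astrocyte
    images with analytically known ground truth and simulated
    sham/PID/EA cohorts so the whole analysis runs end to end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    EBImage,
    tiff,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
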