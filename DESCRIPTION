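Package: maizecfi
Title: Organ-Level Trait Extraction from Maize Chlorophyll Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Maize Phenomics Contributors", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Segmentation and organ-level trait extraction for single-plant
    side-view chlorophyll fluorescence images (CFI) of maize. Plants fluoresce
    brightly against a dark background, which permits fully automatic Otsu
    thresholding; the resulting mask is skeletonized and its landmarks (leaf
    tips, branch points, stem start, top node) drive a geodesic-distance stem
    path extraction, distance-transform stem diameter estimation, and
    bottom-up labeling of fully expanded leaves with per-leaf area and
    tip-to-stem angle. Includes whole-plant traits (height, width,
    side-projected area), top-view orientation from the convex hull, a
    procedural synthetic corn-plant renderer with exact per-organ ground
    truth, batch processing, and evaluation against ground-truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    igraph,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
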