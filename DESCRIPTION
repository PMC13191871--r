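Package: moltrack
Title: Multi-Object and Lineage Tracking for Segmented 2D and 3D Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training-free, overlap-based tracking of object instances in
    time series of 2D or 3D instance-segmentation label images, as a
    post-processing step after any segmentation method. Per-frame affine
    registration (to a reference frame for jointly-moving scenes, or
    pairwise for independently moving objects) is followed by union-map
    construction, graph-based conflict resolution into lineages, per-lineage
    morphogenetic graphs with split/merge/appear/vanish event
    classification, and temporally consistent tracked identifiers projected
    back into the native image space. Includes lineage-reconstruction (LNR)
    and acyclic-oriented-graph-matching (AOGM/TRA) evaluation metrics, a
    synthetic scenario generator with full ground truth, readers and
    writers for per-frame TIFF label images and Cell Tracking Challenge
    track tables, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
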