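Package: spotseg
Title: Multi-Scale Manifold Cell Segmentation for Imaging-Based Spatial
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Assigns individual RNA molecules ("spots") detected by
    imaging-based spatial transcriptomics assays (STARmap, MERFISH and
    similar) to individual cells.  Each spot is described by a multi-scale
    neighborhood gene composition (MSNGC) feature; physical Manhattan
    distance is fused with MSNGC correlation into a spatial-transcriptomic
    distance, from which a fuzzy k-nearest-neighbor manifold graph is
    built, embedded into a low-dimensional clustering space by minimizing
    a cross-entropy objective, and segmented with density-based clustering
    (DBSCAN).  Includes clustering evaluation metrics (adjusted Rand
    index, normalized mutual information, silhouette coefficient), a
    synthetic spot-cloud simulator with per-spot ground truth, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    methods,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    cluster,
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
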