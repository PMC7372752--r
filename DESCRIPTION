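Package: EigenTAD
Title: Hierarchical TAD Calling from Hi-C Contact Matrices via Windowed
    Spectral Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects topologically associated domains (TADs) and their
    hierarchy in chromosome-level Hi-C contact matrices. A sliding window is
    moved along the matrix diagonal; within each window the symmetric
    normalized Laplacian is eigendecomposed, eigenvector rows are projected
    onto the unit circle, and gaps between consecutive projections propose
    TAD boundaries. The number of TADs per window is chosen automatically by
    maximizing the mean silhouette score under a contact-based distance.
    Sub-TADs are found recursively from Z-scores of log eigenvector gaps.
    Includes matrix balancing (ICE, Knight-Ruiz, square-root vanilla
    coverage), plain-text Hi-C matrix readers and writers, a synthetic
    block-matrix generator with known ground truth, and evaluation utilities
    (Jaccard and cross-resolution Jaccard boundary comparison, noise /
    sparsity / downsampling perturbations, and a permutation test for
    enrichment of genomic annotations at boundaries).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    rtracklayer,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
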