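Package: scmtop
Title: Single-Cell Morphological and Topological Profiling of Whole-Slide Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-cell profiling of segmented nuclei from H&E whole-slide
    images. Reads nuclear segmentation output (centroid, contour, type per
    nucleus), computes per-nucleus morphological and gray-level co-occurrence
    texture features, builds multilevel pairwise k-nearest-neighbor cell
    graphs between tumor, inflammatory and stroma cells and extracts per-cell
    topological features. Downstream analyses include Leiden cell clustering
    with fixed-membership extrapolation, a morphological intratumor
    heterogeneity (MITH) statistic, spot-level multivariate spatial
    correlation and Moran's I, discovery of micro-ecological modules (MEMs)
    by hierarchical clustering of cluster colocalization, and MEM-composition
    ecotype classification with an SVM. A seeded synthetic-field generator
    produces marked point patterns, contours and texture patches so the whole
    pipeline is testable without slide data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    data.table,
    e1071,
    cluster,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
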