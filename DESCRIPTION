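Package: treedeconv
Title: Tree-Guided Weighted NNLS Deconvolution of Bulk RNA-Seq with
    Single-Cell References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates cell-type proportions in bulk RNA-seq samples from an
    annotated single-cell reference. Marker genes are selected per cluster by
    repeated bootstrap draws of background clusters scored with Wilcoxon
    rank-sum tests and a density-based (DBSCAN) outlier analysis; proportions
    are recovered by weighted non-negative least squares on the marker genes,
    weighting each gene by its cross-subject and cross-cell variation, with an
    optional two-level tree-guided procedure (coarse cluster groups first,
    member clusters within each group). Includes a negative-binomial
    multi-subject single-cell simulator with planted markers, exact-mixture
    and cell-sampling pseudo-bulk generators with known ground-truth
    proportions, and a parameter-tuning grid driven by recovery metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    pracma,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
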