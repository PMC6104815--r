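Package: macIdent
Title: Identity Erosion Analysis for Tissue-Resident Macrophages in Mosaic
    Conditional Knockouts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies how a conditional gene deletion erodes the
    tissue-specific identity of macrophage populations profiled by
    single-cell RNA-seq. Provides median-absolute-deviation quality
    control, size-factor log-normalisation, highly variable gene
    selection, PCA and kNN label-propagation clustering, genotype-group
    assignment of mosaic CRE+ samples (knockout versus heterozygous
    escaper cells), Wilcoxon rank-sum differential expression with
    Benjamini-Hochberg correction, derivation of conserved-core and
    tissue-specific identity signatures from bulk profiles with
    confounded-tissue exclusion, identity-erosion scoring, origin-gene
    subtraction and cross-tissue conservation partitions. A negative
    binomial simulator with full ground truth emulates mosaic knockout
    experiments for benchmarking and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    igraph,
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    scater,
    mclust,
    withr
biocViews: SingleCell, Transcriptomics, DifferentialExpression,
    QualityControl, Clustering
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
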