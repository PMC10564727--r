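Package: limbatlas
Title: Cross-Species Single-Cell Limb Atlas Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating a cross-species single-cell
    atlas of the developing and regenerating vertebrate limb. Provides a
    synthetic multi-species count-data generator with known ground truth, a
    shared gene-space builder that collapses homeologs and duplicate
    transcripts, per-dataset preprocessing with cell-cycle-correlated
    principal-component correction, mutual-nearest-neighbour integration,
    neighbour-voting AUROC cluster replicability scoring, per-cell AUC
    gene-set enrichment, consensus non-negative matrix factorization for
    transcriptional program discovery, gene-set projection with a
    cross-lineage aggregation statistic, and Visium-style spatial spot
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    cluster,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    uwot,
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, GeneExpression, Clustering,
    DimensionReduction, Spatial
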