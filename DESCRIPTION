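Package: scEngram
Title: Cell-Type Taxonomy and Fear-Memory Engram Analysis for Single-Cell
    RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct a neuronal cell-type taxonomy from UMI
    count matrices (iterative quality control, class assignment by marker
    vote, CV-mean feature selection, PCA, batch correction, t-SNE embedding,
    density-based cluster calling, dendrograms and branch-point markers), to
    map cluster expression profiles onto spatial transcriptomics spots and
    in situ hybridization voxel atlases by Pearson correlation, and to
    quantify fear-conditioning engram signatures: percentile-based
    immediate-early-gene activation calling, cluster IEG scores,
    observed-versus-expected activation enrichment, in-silico trapping
    differential expression of activated cells, gene-module correlation
    scores, and event-aligned fiber-photometry z-scoring. A seeded
    synthetic-data generator with planted ground truth (cell types, engram
    subsets, coregulated modules, batch effects, doublets, spatial regions,
    voxel atlases, photometry traces) supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    Rtsne,
    irlba,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
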