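Package: svfcomm
Title: Cell-Cell Communication Inference for Stromal Vascular Fraction
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for inferring intercellular communication
    from droplet single-cell RNA-seq of adipose stromal vascular fraction
    (SVF) cells. Implements Seurat-style preprocessing (QC filtering,
    log-CPM normalization with a one-million scale factor, covariate
    regression, highly variable gene selection, PCA, shared
    nearest-neighbor graphs and Louvain clustering), construction of a
    weighted directed ligand-receptor communication graph between cell
    types (fold-change weighted source and target edges, STRING-style
    association scores on ligand-receptor edges), permutation-based
    significance of cell-type connections with Benjamini-Hochberg
    adjustment, and incoming/outgoing communication-strength summaries.
    Ships a negative-binomial synthetic SVF data generator with planted
    ligand-receptor signals so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
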