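Package: cytomodules
Title: Immune Subset Discovery, Co-Abundance Networks and Label Transfer
    for Mass Cytometry
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for sample-level analysis of mass cytometry (CyTOF)
    studies of intestinal and blood immune cells: a ground-truth-bearing
    synthetic study generator built on a logistic-normal composition model
    with latent co-abundance modules, arcsinh preprocessing and CD45
    gating, two-level subset identification (lineage assignment followed
    by Gaussian-mixture clustering with BIC model selection), differential
    abundance with Benjamini-Hochberg FDR control and Kruskal-Wallis/Dunn
    tests, Spearman correlation networks over subset frequencies with
    module extraction and qualification, linear discriminant analysis
    label transfer with a posterior-probability rejection option,
    sample-level t-SNE/PCA embeddings with replicate QC, and Hotelling
    two-sample T2 tests on reduced sample spaces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    SummarizedExperiment,
    mclust,
    cluster,
    clue,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pheatmap,
    withr,
    optparse
Config/testthat/edition: 3
biocViews: SingleCell, FlowCytometry, Proteomics, Clustering,
    DifferentialExpression, Network, Classification
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'panel.R'
    'catalog.R'
    'cytomodules-package.R'
    'utils.R'
    'ingest.R'
    'diffabund.R'
    'embed.R'
    'identify.R'
    'lda.R'
    'network.R'
    'simulate.R'
    'pipeline.R'
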