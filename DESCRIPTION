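Package: netmark
Title: Gene Subnetwork Biomarker Identification from Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies gene-subnetwork biomarkers from case/control or
    multiclass expression data by integrating gene sets and a gene-gene or
    protein-protein interaction network. Subnetworks are grown from
    high-degree significant seed genes by one of three expansion strategies
    (greedy, gene-set-based, parent-node-based), scored by the one-way ANOVA
    F statistic of a signed z-score activity vector. Includes an evaluation
    harness (normalized cluster-purity dataset homogeneity, gene and
    gene-set level agreement, cross-dataset SVM classification reported as
    ROC AUC) and a synthetic benchmark generator with planted
    differentially-active connected modules on scale-free networks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    igraph,
    jsonlite,
    e1071,
    pROC,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
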