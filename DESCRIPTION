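Package: layerscope
Title: Layered Molecular Subtyping of Tumor Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discovers independent "layers" of biological information in
    multi-cohort tumor gene-expression data. Provides preprocessing for merged
    microarray cohorts (probe collapse, batch-mean correction, variability
    filtering), a decomposable Gaussian graphical model built from a
    maximum-likelihood spanning tree followed by a BIC forward edge search,
    functional-node activities, iterative sparse k-means plus consensus
    clustering that peels one layer of sample structure at a time, permutation
    based differential expression (SAM), Kruskal-Wallis/Dunn node-activity
    comparisons, hypergeometric gene-set labeling, and Kaplan-Meier/log-rank
    survival stratification of the discovered groups. A synthetic cohort
    generator with planted layer structure, batch effects and group-dependent
    survival supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    igraph,
    survival,
    mclust,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
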