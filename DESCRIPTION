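Package: methylDeviance
Title: Blood Methylation EWAS with Region-Level Deviance-Accumulation Testing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An epigenome-wide association workflow for Illumina
    Infinium 450K blood methylation case/control cohorts, built around a
    region-level differential methylation test that accumulates independent,
    possibly opposite-sign CpG-site effects through the deviance difference of
    nested binomial regressions. Provides quality-control filtering with a
    conservation-checked ledger, M-value computation, reference-based
    cell-type deconvolution, residual-PCA surrogate variables, moderated
    site-level models with discovery/cross-validation replication and
    fixed-effect meta-analysis, site pooling, OPLS-DA classification with
    elastic-net subset selection, and a shrinkage partial-correlation keyword
    network. Includes a seeded synthetic-cohort generator so the whole
    pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    limma,
    glmnet,
    pracma,
    data.table,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    metafor,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics,
    MethylationArray, Classification, GraphAndNetwork
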