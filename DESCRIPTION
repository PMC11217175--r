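Package: ChemoResNet
Title: Blood Transcriptome Chemoresistance Analysis with Co-Expression
    Hub Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for paired pre/post-treatment blood
    transcriptome cohorts stratified by chemotherapy resistance pattern
    (primary versus acquired), as used in small-cell lung cancer studies.
    Provides quantile normalization and (moderated) differential
    expression with fold-change and FDR thresholds, single-sample
    gene-set enrichment scoring of user-supplied cell-type and pathway
    signatures, correlation-based co-expression networks with two-stage
    edge filtering and spanning-forest hub-gene discovery, median-split
    Kaplan-Meier / log-rank progression analysis, and a seeded synthetic
    cohort generator with planted ground truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
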