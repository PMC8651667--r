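Package: fundisc
Title: Functional Gene Discovery from Temporal Transcriptome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for discovering novel functional genes from
    multi-batch temporal RNA-seq count data: negative-binomial batch correction
    by quantile mapping, two-group Wald differential expression with
    median-of-ratios normalization, TPM/z-score temporal profile construction,
    gap-statistic selection of the cluster number, hierarchical clustering of
    expression profiles, per-cluster hypergeometric gene-ontology
    over-representation, and prediction of unannotated candidate genes from
    clusters that carry known functional genes.  Includes a seeded
    negative-binomial simulator with planted temporal modules and ground truth
    for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    S4Vectors,
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
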