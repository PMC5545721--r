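Package: coexpci
Title: Co-Expression Modules and the Polygenic Co-Expression Index
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects a seed-gene weighted co-expression module in a gene
    expression matrix, summarizes it by its module eigengene (first principal
    component), screens SNPs for association with the eigengene (co-eQTLs),
    and combines independent associated SNPs into a Polygenic Co-expression
    Index (PCI) that predicts module co-expression from genotype alone.
    Includes cross-validation and frozen-weight replication of the index,
    hypergeometric risk-gene enrichment, phenotype association tools
    (robust and ordinary linear models, two-level repeated-measures
    interaction tests, Spearman correlation, ROC/AUC, false discovery rate
    control), a synthetic-cohort generator with the generative structure the
    analysis assumes, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    MASS,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    vcfR,
    yaml,
    optparse,
    withr,
    car
Config/testthat/edition: 3
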