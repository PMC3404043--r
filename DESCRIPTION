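Package: stratDE
Title: Stratified Fold-Change Differential Expression for Low-Input
    Oocyte Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Differential-expression calling for read-count tables from
    low-input transcriptome experiments without biological replicates,
    as used in two-model diabetic mouse oocyte studies. Genes passing a
    strict detection filter (summed reads > 10) are split into high- and
    low-expression strata at 1/10 of the mean per-gene count, and called
    up- or down-regulated by stratum-specific log2 fold-change cutoffs
    (0.8 for the high stratum, 2 for the low stratum). Downstream tools
    provide one-sided Fisher exact (hypergeometric) gene-set
    over-representation with optional GO-slim collapsing, cross-model
    overlap classification with KEGG-style color-class export, and
    sequencing-vs-qPCR concordance. A negative-binomial synthetic-data
    generator with planted differential expression, planted enriched
    terms and simulated qPCR replicates makes the whole pipeline
    testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment
Suggests:
    withr,
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
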