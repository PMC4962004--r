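Package: ribolnc
Title: Discovery and Differential Analysis of Long Noncoding RNAs from
    Pooled RNA-Seq Transcript Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate long noncoding
    RNAs (lncRNAs) and novel mRNAs from bulk RNA-seq transcript models in
    a two-breed design: pooling of per-sample/per-assembler transcript
    models with a reliability rule, a multi-stage filter cascade (read
    coverage, exon number, length, annotation removal) with a
    four-scorer coding-potential consensus, FPKM quantification and
    expression-set summaries, exact negative-binomial differential
    expression with Benjamini-Hochberg FDR, cis target prediction for
    differentially expressed lncRNAs within a 100 kb window, local
    alignment homology classification with Karlin-Altschul E-values,
    hypergeometric term enrichment, and phenotype/qPCR summary
    statistics. Ships a synthetic-data generator with recorded ground
    truth that emulates the study design end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    edgeR,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
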