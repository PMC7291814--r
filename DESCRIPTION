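Package: PopSplice
Title: Population-Scale Alternative Splicing: Event Classification,
    Heritability and Splicing QTL
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing alternative splicing across a replicated
    population expression study. Classifies the five canonical splicing
    event types (retained intron, skipped exon, alternative donor and
    acceptor, alternative terminal exon) from a transcript annotation,
    applies junction-support and retained-intron coverage filters,
    performs presence/absence and major-isoform analyses of isoform FPKM
    matrices, estimates broad-sense heritability of isoform expression by
    REML variance components with a genotype-permutation null, maps
    isoform-expression and splice-junction-usage QTL with an empirical
    permutation FDR and cis/trans classification, and computes gain and
    loss of protein domains and miRNA binding sites between isoforms with
    attribution to splicing events. Includes a self-consistent synthetic
    study generator with recorded ground truth and an end-to-end pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), GenomicRanges, SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, IRanges, rtracklayer, lme4,
    vcfR, data.table, jsonlite, yaml
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
biocViews: AlternativeSplicing, GeneExpression, Genetics, SNP,
    Transcriptomics, Software
RoxygenNote: 7.3.3
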