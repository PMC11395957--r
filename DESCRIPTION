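Package: sturgeonGP
Title: Mixed-Model GWAS and Feature-Informed Genomic Prediction for Aquaculture Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for dense-SNP analysis of quantitative traits in
    aquaculture breeding populations: genotype input and quality control (MAF
    and exact Hardy-Weinberg filters), VanRaden genomic relationship matrices,
    linkage-disequilibrium pruning and decay summaries, average-information
    REML variance components and SNP heritability, single-marker mixed-linear-
    model association scans with polygenic control and inflation diagnostics,
    candidate-gene windows against a GFF3 annotation, and genomic prediction by
    GBLUP, GBLUP on an LD-pruned marker subset (GLDBLUP), and genomic-feature
    BLUP (GFBLUP) with per-fold FDR marker preselection, evaluated by
    replicated k-fold cross-validation. Includes a calibrated genotype and
    phenotype simulator with distance-decaying LD and known QTL architecture
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
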