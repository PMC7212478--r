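Package: cloneDiverge
Title: Multi-Omics Divergence Analysis of Tumor Subclones
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint analysis of somatic point mutations, allele-specific copy
    number, CpG methylation, and expression counts for a small panel of tumor
    subclones sharing one matched normal. Reconstructs the clonal phylogeny by
    Wagner (Fitch) parsimony on the SNV presence/absence matrix after masking
    loss-of-heterozygosity regions, quantifies transcriptome and methylome
    divergence by hierarchical clustering, detects differentially methylated
    sites and functional categories with Fisher exact tests, tests copy-number
    dosage effects on expression with one-sided Kolmogorov-Smirnov statistics,
    and classifies sample-specific expression changes as copy-number-driven or
    gene-body-methylation-driven by directional consistency. A synthetic-data
    generator plants a known clonal tree, copy-number events, methylation
    differences, and methylation-expression couplings so that every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    ape,
    data.table,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
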