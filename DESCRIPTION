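Package: wingscan
Title: Introgression Mapping and Dating of the Pigeon Checker Wing-Pattern Haplotype
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to localize the rock pigeon (Columba livia) wing-pattern
    locus and characterize the interspecies origin of the checker haplotype:
    allele-frequency differentiation scans with genome-wide thresholds,
    minimal shared haplotype delineation, four-taxon ABBA-BABA D-statistics
    with moving-blocks bootstrap confidence intervals, triplet sequence
    similarity scanning, coalescent SNP-count dating, extended haplotype
    homozygosity (EHH) and linkage-disequilibrium-decay haplotype age
    estimation with binomial confidence intervals, copy-number genotyping
    from normalized read depth, and qPCR / allele-specific expression
    analyses. Includes a structured-coalescent quartet simulator with a
    known introgression pulse so every pipeline stage is testable without
    sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    VariantAnnotation,
    minpack.lm
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
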