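Package: selsig
Title: Selection-Signature Scanning in Multi-Breed SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-arm selection-signature pipeline for multi-breed SNP-array
    data. The diversifying-selection arm computes per-SNP pairwise
    Weir-Cockerham FST, the breed-standardized d_i statistic, 10-SNP sliding
    windows and empirical 99.9th-percentile region calling. The within-breed
    arm detects core haplotypes (3-20 SNPs), computes extended haplotype
    homozygosity (EHH) and relative EHH (REHH) at about 1 Mb, and assigns
    frequency-bin empirical P-values. Includes SNP quality control (MAF,
    missingness, exact Hardy-Weinberg tests), population-structure summaries
    (PCA, neighbor-joining from FST distances), interval bookkeeping with
    annotation overlap, and a synthetic multi-breed phased-haplotype
    generator (Balding-Nichols frequencies plus founder-mosaic haplotypes,
    optional hard-sweep injection) so every stage is testable without
    external genotype downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    data.table,
    jsonlite,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    ggplot2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
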