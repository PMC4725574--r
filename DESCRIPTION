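Package: karyoCNV
Title: Chromosomal Anomaly Detection and CNV Burden Analysis for SNP
    Arrays
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects sex-chromosome and autosomal aneuploidy, whole-chromosome
    uniparental isodisomy and mosaicism from per-chromosome log R ratio and
    B allele frequency summaries of SNP-array intensity data; builds
    multi-algorithm consensus copy-number-variant (CNV) sets with tiered
    size/marker filters, rarity classes and gene/region annotation; and runs
    the case-control statistical layer: exact 2x2 tests with sample and
    conditional-MLE odds ratios, permutation CNV-burden testing over a
    3 contrasts x 3 CNV classes x 7 statistics grid with Bonferroni control,
    linear genotype-phenotype association with spectral-decomposition
    (effective number of tests) correction, and power calculations. A
    synthetic-array module simulates Illumina-like LRR/BAF signal for
    arbitrary karyotypes (45,X; 47,XXY; 47,XXX; mosaics; uniparental
    isodisomy; segmental CNVs) with a complete truth table, so every
    detection and statistical layer is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
biocViews: CopyNumberVariation, SNP, QualityControl, StatisticalMethod,
    GenomeWideAssociation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
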