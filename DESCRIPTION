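Package: windowscan
Title: Sliding-Window Variant-Set Association Tests for Survival and
    Expression Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Region-based association testing of SNP sets against
    right-censored survival and quantitative expression phenotypes in
    small resequenced cohorts. Enumerates sliding windows of 10-50
    markers over a gene region, tests each window with a
    difference-in-minor-allele-frequency (DMAF) statistic against a
    median-dichotomized expression phenotype and with a minor-allele
    burden score in a Cox proportional-hazards likelihood-ratio test,
    calibrates both by phenotype permutation with per-window-size
    max-statistic family-wise error control, and prioritizes candidate
    regulatory SNPs by transcription-factor-site annotation and
    linkage-disequilibrium cross-filtering. Includes a seeded synthetic
    cohort generator emulating the sample structure the tests assume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
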