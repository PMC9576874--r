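Package: teloscan
Title: Genetic and Epigenetic Regulation of Newborn Telomere Length
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A four-step candidate-gene analysis of newborn telomere length
    (T/S ratio) against SNP genotypes and cord-blood DNA methylation:
    covariate-adjusted SNP-telomere association under dominant and additive
    coding, cis-mQTL mapping with empirical-Bayes moderated inference and
    Bonferroni control, causal mediation through CpG methylation with
    bootstrap-percentile inference, and SNP-by-CpG effect-modification
    scanning. Includes the genotype QC chain (call rates, empirical
    imputation, MAF and Hardy-Weinberg filters, LD r2), the methylation QC
    chain (M-values, detection filtering, KNN imputation, empirical-Bayes
    batch/position adjustment, IQR trimming, probe blacklists,
    reference-based cord-blood cell-type deconvolution), and a synthetic
    cohort generator with known ground truth for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    jsonlite,
    withr,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    limma,
    sva
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
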