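Package: gwasinflate
Title: Genomic Inflation Correction and Its Cost in GWAS Meta-Analyses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify genomic inflation in genome-wide association
    study (GWAS) meta-analysis summary statistics and to measure what
    correcting for it costs in statistical power. Implements the genomic
    control lambda (median chi-square ratio), un-correction and re-correction
    of GC-corrected p-values on the chi-square scale, LD-score regression
    (LDSC-style intercept estimation with two-step weights and block
    jackknife), intercept correction, pairwise confirmation of associations
    between an earlier and a later study (robust/false-positive accounting,
    FPR/TPR), a leave-one-chromosome-out resampling null with empirical
    p-values, PLINK-style greedy LD clumping, and an independent-loci loss
    report with MHC and single-variant-clump exclusions. A synthetic
    summary-statistics generator with block LD structure and known
    confounding/heritability supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
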