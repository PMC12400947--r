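Package: gdiqc
Title: Batch-Level Quality Control for Genotypes Imputed from Low-Pass
    Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quality control of genotypes imputed from ultra-low-coverage
    (<1x) whole-genome sequencing, such as cell-free DNA from noninvasive
    prenatal screening. Implements the GDI batch-level filtering strategy,
    which combines a cross-batch INFO-score exclusion, per-genotype
    consistency flags on the posterior genotype probability (GP) and the
    alternate-allele dosage (DS), per-sample low-quality-variant (LQV)
    scoring with outlier removal, and exclusion of variants flagged in too
    large a fraction of samples. Also provides the individual-level
    max(GP) filter for comparison, cumulative-missingness accounting,
    post-imputation accuracy metrics against truth genotypes (sensitivity,
    precision, non-reference concordance, dosage r-squared, stratified by
    minor-allele-frequency bin and genotype class), and a synthetic
    low-pass imputation simulator with Poisson read depth, base-calling
    error and maternal-plasma fetal-fraction contamination, so the whole
    pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
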