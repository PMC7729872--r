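Package: pqtlkit
Title: Protein Quantitative Trait Locus Discovery, Calibration and
    Downstream Inference for Sequencing Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for mapping protein quantitative trait
    loci (pQTLs) in whole-genome-sequenced cohorts, with particular
    attention to isolated populations.  Provides phenotype preparation for
    Olink-style NPX protein panels (limit-of-detection censoring,
    covariate adjustment, inverse-normal transformation), linear mixed
    model single-variant score scans with an empirical genetic
    relationship matrix, signal extraction and approximate
    conditional/joint stepwise selection from summary statistics,
    functionally weighted SKAT-O rare-variant burden testing under the
    mixed model, eigenvalue-based effective-trait multiple-testing
    calibration, replication assessment, allele-frequency divergence
    statistics, two-sample Mendelian randomization, and polygenic score
    construction, validation and disease screening.  A fully seeded
    synthetic-cohort generator emulating LD-structured genotypes, cryptic
    relatedness, isolate allele-frequency drift and censored protein
    panels supports calibration studies and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
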