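Package: hlaimpute
Title: Ancestry-Aware HLA Genotype Imputation and Molecular Mismatch
    Deviation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how much error haplotype-frequency-based HLA
    genotype imputation introduces into molecular mismatch scores under
    correct, incorrect, broad, and pooled ("SUPER") ancestry assumptions.
    Provides a five-locus HLA nomenclature layer (A, C, B, DRB1, DQB1),
    population haplotype-frequency tables with pooling, simulation of
    patient-donor cohorts from frequency tables, single/multiple/strict
    imputation with a stepwise linkage-relaxation fallback, T-cell
    (PIRCHE-II-style) and B-cell (surface-exposed mismatch, Snow-style)
    epitope scorers with frequency-weighted aggregation over imputed
    genotype sets, and an evaluation layer (allele mismatches, log-delta
    deviations, noticeable-deviation proportions, classification metrics,
    and reliability percentile curves) grouped by true and assumed ancestry.
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
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
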