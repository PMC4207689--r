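Package: hybridase
Title: Cis- and Trans-Regulatory Divergence and Imprinting from F1 Hybrid
    Allele-Specific Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian classification of gene-regulatory divergence from
    allele-specific RNA-seq of F0 homozygotes and reciprocal F1 hybrids.
    Genes are classified as conserved, cis, trans, or cis-and-trans by
    closed-form Gaussian model comparison on replicate-level log-expression
    summaries with known measurement variance; parent-of-origin (imprinting)
    effects are detected from reciprocal crosses by Bayes factors and
    filtered before classification. Includes inverse-variance-weighted log2
    fold-change estimation with subcategorization of combined cis and trans
    effects, cross-tissue effect-sharing comparison, peak-to-gene assignment
    for cis-regulatory elements, variant-density profiling in regulatory
    windows, enrichment tests, a seeded synthetic-data generator with known
    ground truth, readers and writers for the tabular, BED and VCF formats
    involved, and a pipeline command-line interface.
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
    jsonlite,
    purrr,
    readr,
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
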