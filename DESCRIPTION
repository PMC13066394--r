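Package: bimr
Title: Bidirectional Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bidirectional two-sample Mendelian
    randomization on GWAS summary statistics: genome-wide-significant
    instrument selection with LD clumping and proxy substitution, allele
    harmonization (including palindromic-variant handling), the
    inverse-variance weighted, MR-Egger and weighted-median estimators,
    Cochran's Q heterogeneity and leave-one-variant-out diagnostics, an
    MR-PRESSO outlier battery, Steiger directionality filtering, a Bayesian
    horseshoe model for correlated pleiotropy, Benjamini-Hochberg FDR across
    test families, and a tiered evidence-classification procedure. Includes
    a synthetic summary-statistics generator with known causal ground truth
    so every stage is testable without external GWAS downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
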