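Package: grsconcord
Title: Platform Concordance Analysis for an HLA-Aware Type 1 Diabetes Genetic Risk Score
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a config-driven Type 1 Diabetes genetic risk score
    (additive variant weights plus HLA DR-DQ diplotype interaction terms)
    from whole-genome-sequencing VCF calls or imputed-array dosages, applies
    sequencing-call quality filters (depth, genotype quality, allelic
    balance), assigns samples to ancestry super-populations by
    reference-projected principal components and a multinomial elastic-net
    classifier, and quantifies cross-platform score concordance: Spearman
    correlations with bootstrap intervals, the Meng-Rosenthal-Rubin test for
    dependent correlations, paired differences, per-variant exact
    allele-frequency tests, Bland-Altman agreement, centile-threshold
    re-categorisation tables, and ROC AUC. Includes a seeded multi-ancestry
    cohort simulator with distinct whole-genome-sequencing and imputed-array
    observation models for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    vcfR,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
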