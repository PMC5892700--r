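Package: pleiometa
Title: Two-Stage Pleiotropic GWAS Meta-Analysis with Antagonistic
    Heterogeneity Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Univariate and pleiotropic meta-analysis of genome-wide
    association statistics for multiple correlated age-related phenotypes
    across several longitudinal cohorts. Implements fixed-effects
    inverse-variance meta-analysis, Fisher p-value combination, omnibus
    chi-square tests with phenotype-based and permutation-based z-score
    correlation matrices, the two combination pathways (across cohorts then
    phenotypes, and across phenotypes then cohorts), and the classification
    of SNPs by antagonistic genetic heterogeneity (HP, HB, HP/HB, M groups),
    together with a multi-cohort individual-level data simulator for
    validating every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
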