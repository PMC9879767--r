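Package: matmr
Title: Two-Sample Mendelian Randomisation of Maternal Circulating
    Exposures on Offspring Birthweight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation of maternal
    circulating exposures (amino acids) on offspring birthweight from GWAS
    summary statistics: reconstruction of effect sizes from z-score
    meta-analyses, instrument selection with LD clumping and proxy
    substitution, allele harmonisation with palindromic-ambiguity handling,
    Wald-ratio / multiplicative random-effects IVW / MR-Egger /
    weighted-median estimation with heterogeneity and influence
    diagnostics, multivariable MR with conditional F-statistics,
    partitioning of maternal and fetal genetic effects via a weighted
    linear model, cross-source instrument-relevance checks, and a
    mother-child duo simulator for calibrating every stage offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'matmr-package.R'
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sumstats.R'
    'instruments.R'
    'mr.R'
    'mvmr.R'
    'validation.R'
    'simulate.R'
    'show-methods.R'
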