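Package: statinmr
Title: Drug-Target Mendelian Randomization of Statin Effects on
    Multi-Omics Traits and Type 2 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-sample Mendelian randomization toolkit for drug-target
    analyses in which genetic variants near a drug's target gene (for
    statins, HMGCR) proxy pharmacological modulation of the exposure.
    Implements GWAS summary-statistic input/output and allele
    harmonization, linkage-disequilibrium estimation from a reference
    panel with greedy clumping and gene-region instrument selection,
    correlated-instrument inverse-variance-weighted, MR-Egger and
    multivariable estimators with generalized Cochran's Q, fixed-effect
    cross-ancestry meta-analysis, mediation by the product of
    coefficients with a delta-method standard error, approximate Bayes
    factor colocalization, SMR/HEIDI and GSMR-style summary-data tests,
    analytic power calculations for binary outcomes, and a synthetic
    two-sample GWAS generator with known ground truth for calibration
    and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
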