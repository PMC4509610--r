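Package: pedscan
Title: Pedigree-Based Genome Scans for Additive, Dominance and Epistatic Effects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Mixed linear model genome scans for quantitative traits in
    pedigreed populations with repeated records. Builds the numerator
    relationship matrix from a pedigree, codes SNP genotypes into
    allele-frequency-corrected additive and dominance covariates, estimates
    polygenic, permanent-environment and residual variance components by
    average-information REML, and tests single-SNP additive and dominance
    effects as well as pairwise additive-by-additive interactions one at a
    time. Includes a closed-form false discovery rate for scan thresholds,
    per-SNP variance partitioning, cross-population individual and segment
    validation, a conditional re-test that exposes interaction signals
    created by linkage disequilibrium with an untyped causal variant, and a
    simulator of pedigrees, LD-structured genotypes and repeated-record
    phenotypes with a known truth ledger for calibration studies.
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
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
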