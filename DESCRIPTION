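Package: sexmr
Title: Sex-Specific Two-Sample Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Two-sample Mendelian randomization (MR) toolkit for
    sex-stratified analyses of insulin-related exposures and
    cardiovascular outcomes. Provides genetic-instrument selection
    (linkage-disequilibrium pruning, Bonferroni-corrected confounder
    screening, curated pleiotropy exclusions), allele harmonization of
    GWAS summary statistics, Wald-ratio based causal estimators
    (inverse-variance weighting with multiplicative random effects,
    weighted median, mode-based estimate, MR-PRESSO outlier detection),
    genetic-risk-score logistic regression on individual-level data,
    fixed-effect meta-analysis, one-tailed sex-difference z-tests, power
    calculations for binary outcomes, and synthetic-data generators that
    emulate the two-sample design for validation without any cohort
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    metafor,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
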