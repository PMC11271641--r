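Package: mrtwosample
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics: reading and validating summary tables, allele harmonization
    with palindromic-variant handling, instrument selection (significance
    filtering, greedy LD clumping against a user-supplied r-squared table,
    F-statistic strength assessment, confounder exclusion lists), causal
    estimation by inverse-variance-weighted meta-analysis of Wald ratios,
    MR-Egger regression, and the weighted-median estimator, sensitivity
    diagnostics (Cochran's Q, Egger intercept test, leave-one-out, funnel
    data, MR-PRESSO global/outlier tests), multiple-testing correction across
    exposure-outcome families, a synthetic two-sample summary-statistics
    generator with known ground truth, and a configuration-driven pipeline
    that writes publication-shaped result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
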