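Package: selenomr
Title: Two-Sample Mendelian Randomization of Selenium Levels and
    Endometrial Cancer Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Summary-statistic two-sample Mendelian randomization (MR)
    toolkit built around the analysis of genetically predicted selenium
    levels and endometrial cancer risk. Reads and validates GWAS summary
    statistics, harmonizes exposure and outcome effects to a common effect
    allele, prunes instruments for linkage disequilibrium and screens them
    against known risk-factor associations, converts Z-score-scale effects
    to beta/SE, and estimates causal effects by Wald ratios,
    inverse-variance weighting (fixed, multiplicative and additive random
    effects), MR-Egger regression and the weighted median, with Cochran's Q,
    the MR-Egger intercept test and the I2GX weak-instrument diagnostic.
    Includes a seeded generator of synthetic two-sample GWAS summary
    statistics with known causal effect and configurable pleiotropy, so
    every estimator and diagnostic can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
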