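Package: mrsuite
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A complete two-sample Mendelian randomization (MR) toolkit for
    GWAS summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping, confounder-trait exclusion), allele
    harmonization with palindromic-SNP handling, six causal estimators
    (per-variant Wald ratios, multiplicative random-effects inverse-variance
    weighted, MR-Egger with intercept test, simple and weighted median with
    parametric-bootstrap standard errors, robust adjusted profile score, and
    MR-PRESSO outlier detection with outlier-corrected re-estimation),
    heterogeneity statistics (Cochran's Q, I-squared), leave-one-out
    sensitivity analysis, funnel and scatter exports, and binary-outcome
    power calculation.  A seeded synthetic summary-statistic generator with
    configurable causal effect, pleiotropy models, LD-block structure and
    palindromic variants makes every pipeline stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
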