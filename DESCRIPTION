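Package: targetmr
Title: Drug-Target Mendelian Randomization with Two-Step Mediation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Cis drug-target Mendelian randomization from GWAS summary
    statistics: instrument selection (genome-wide significance filter,
    gene-window restriction, greedy LD clumping), exposure-outcome
    harmonization with palindromic SNP removal, the four standard
    two-sample MR estimators (inverse-variance weighted, MR-Egger,
    weighted median, weighted mode) with heterogeneity, pleiotropy and
    leave-one-out diagnostics, and two-step product-of-coefficients
    mediation with prerequisite and sign-consistency gating.  Includes a
    synthetic GWAS summary-statistic generator with known truth so every
    stage can be validated end-to-end, and a config-driven study runner
    with a positive-control gate and full audit logging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
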