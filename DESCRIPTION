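Package: mrscreen
Title: Proteome-Wide Two-Sample Mendelian Randomization with Mediation
    and Phenome-Wide Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) screens of
    many exposures (such as plasma-protein pQTL datasets) against a
    disease outcome from GWAS summary statistics: genome-wide-significant
    instrument selection with greedy LD clumping, allele harmonization
    with removal of palindromic and duplicated variants,
    inverse-variance-weighted and Wald-ratio causal estimation with
    Cochran's Q, MR-Egger intercept and leave-one-out sensitivity
    analyses, two-step MR mediation with product-of-coefficients indirect
    effects and delta-method inference, and phenome-wide (PheWAS-style)
    multi-outcome scans. Includes a summary-statistics simulator with
    known causal structure so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
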