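Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening of Metabolite GWAS
Version: 0.1.0
Authors@R:
    person("mrscreen", "developers", email = "mrscreen@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for two-sample Mendelian randomization
    screens of many exposures (e.g. serum metabolites) against a single
    binary outcome from GWAS summary statistics. Implements instrument
    selection (p-value filtering, LD clumping against a user-supplied LD
    source, F-statistic filtering, exclusion of outcome-associated
    variants), allele harmonization, four causal-effect estimators
    (inverse-variance weighted, MR-Egger, weighted median, MR-PRESSO), a
    sensitivity suite (Cochran's Q, Egger intercept, leave-one-out,
    Steiger directionality), Bonferroni multiple-testing control with a
    strong/robust/potential classification rule, and a synthetic
    summary-statistics generator with known ground truth for validation.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
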