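Package: mrmediate
Title: Two-Sample Mendelian Randomisation and Two-Step Mediation for
    Birth Weight and Cardiovascular Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summary-statistics Mendelian randomisation toolkit built around
    a two-step mediation design: instrument selection and harmonisation of
    GWAS summary statistics, univariable estimators (Wald ratio,
    inverse-variance weighted, MR-Egger, weighted median, weighted mode)
    with heterogeneity and pleiotropy diagnostics including MR-PRESSO,
    multivariable MR by weighted least squares, product-of-coefficients
    mediation with delta-method standard errors, and a seeded synthetic
    GWAS generator with analytic ground truth so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
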