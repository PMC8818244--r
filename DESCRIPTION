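Package: dxverify
Title: Diagnostic Test Accuracy with Suspect Results and Verification Bias
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates diagnostic-test accuracy for three-category tests
    (positive / suspect / negative) and corrects for partial and
    differential disease-verification bias. Implements conditional
    (3x2) performance measures and test yields, the Begg-Greenes
    redistribution for 2x2 tables together with its 3x2 extension to
    suspect results, multiple imputation by chained equations with
    Rubin pooling, and a Bayesian model linking index-test accuracy,
    prevalence and an imperfect reference standard. Ships the
    verification table of a fine-needle-aspiration-cytology breast
    cancer cohort as a built-in example, a synthetic cohort generator
    with a missing-at-random verification mechanism for method
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
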