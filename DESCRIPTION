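Package: maxlogit
Title: Max-Logistic Competing-Factor Classifiers for Minimal Gene Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the max-logistic competing risk-factor classifier for
    minimal gene-expression biomarker panels: each competing factor is a linear
    combination of a few genes, a sample's score is the maximum over factors,
    and the logistic of that maximum is the disease-risk probability. Provides
    panel scoring and evaluation, specificity-constrained panel fitting with
    greedy factor addition and exhaustive gene-subset search, unpooled
    cohort-to-cohort cross-validation with coefficient-sign consistency checks,
    a seeded synthetic cohort generator with case-subgroup heterogeneity and
    tissue-dependent sign reversal, qPCR relative-quantification helpers, and
    bundled fixtures for a published sepsis plasma cohort and its classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
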