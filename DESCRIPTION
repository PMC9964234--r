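Package: ccrewire
Title: Gene-Pair Correlation Rewiring Analysis for Multi-Condition
    Expression Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential gene-pair correlation analysis for expression
    studies with repeated conditions (e.g. before / during / after an
    exposure). Builds per-condition Pearson correlation matrices, their
    elementwise differentials (delta-CC), classifies pair transitions by
    sign and correlation-strength class, and applies a two-stage screen
    (|delta-CC| cut, then strength-class transition rule) to assemble a
    compact biomarker gene panel. Includes a likelihood-ratio
    differential-expression stage, GMT gene-set handling, a synthetic
    three-condition study generator with planted correlation transitions
    for validation, and the published pair-correlation values of the
    E-GEOD-74708 astronaut study as a worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
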