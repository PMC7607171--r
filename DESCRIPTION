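Package: tgmo
Title: Therapeutically Guided Multidrug Optimization for Low-Dose Drug
    Combination Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, modelling and interpreting phenotypic
    low-dose drug-combination screens. Builds orthogonal-array composite
    designs (a resolution-IV two-level fractional factorial joined to a
    27-run three-level orthogonal array), fits stepwise second-order
    response-surface regressions of cell viability for tumor cells,
    nonmalignant cells and their difference (the therapeutic window),
    diagnoses fitted models (lack-of-fit ANOVA, Cook's-distance outlier
    variants, residual summaries), classifies drug-drug interactions,
    iteratively eliminates drugs across search rounds to select an
    optimized drug combination, refines its doses on the fitted surface,
    and scores combination effects by Bliss independence. Includes
    single-drug dose-response fitting (four-parameter logistic) with
    plasma-concentration-limit dose capping, and seeded synthetic-data
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
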