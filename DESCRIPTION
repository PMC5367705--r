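Package: nwas
Title: Neighborhood-Wide Association Studies for Area-Level Disease Risk Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An agnostic, three-phase screening framework for testing
    thousands of area-level (census-tract) variables for association with a
    binary health outcome, modeled on genome-wide association studies. Phase 1
    screens every variable with a generalized estimating equation logistic
    model (exchangeable working correlation, robust sandwich variance,
    Bonferroni correction); Phase 2 re-evaluates Phase 1 hits with a Bayesian
    hierarchical logistic model carrying county-level iid and intrinsic
    conditional autoregressive (ICAR) spatial random effects, judged by
    Bonferroni-level credible intervals; Phase 3 groups surviving variables by
    principal components and reports one representative "top hit" per
    component. Includes readers and writers for registry, exposure and
    geography tables, an auditable preprocessing cascade, and a synthetic-data
    generator with planted effects for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
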