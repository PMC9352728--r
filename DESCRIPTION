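Package: deerens
Title: Two-State Conformational Equilibria from DEER, PRE and
    Ensemble-Averaged Distance Restraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative magnetic-resonance analysis of two-domain
    conformational equilibria. Simulates and inverts double
    electron-electron resonance (DEER) dipolar time traces into two-state
    distance distributions with populations, using a bi-Gaussian
    parametric model and non-negative Tikhonov regularization with
    generalized cross-validation, plus residual-resampling bootstrap
    confidence intervals. Converts paramagnetic relaxation enhancement
    (PRE) rates into population-averaged distance restraints via the
    Solomon-Bloembergen relation, builds ensemble-averaged NOE/PRE/DEER
    distance restraints, and evaluates and optimizes two-state rigid-body
    conformer ensembles against them with a sum-of-squared-violations
    target function. A synthetic-data generator produces ground-truth
    two-domain systems and all downstream measurements so the full
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    bio3d,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
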