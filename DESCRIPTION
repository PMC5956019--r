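Package: mstbind
Title: Binding Affinity Analysis for Microscale Thermophoresis and
    Equilibrium Dialysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying antibody-hapten binding affinities from
    microscale thermophoresis (MST) and equilibrium dialysis experiments.
    Converts raw thermophoresis fluorescence traces to normalized
    fluorescence (F_norm) with capillary-level quality control, fits
    saturation binding curves with explicit ligand depletion to obtain
    dissociation constants (K_d), fits competition curves to obtain IC50
    values and converts them to competitor affinities (K_i) through an
    exact ternary-equilibrium model, estimates antibody binding-site
    concentrations from equilibrium-dialysis partitioning via Mueller's
    equation, and analyses first-order drug degradation kinetics with
    half-life confidence intervals. Includes seeded synthetic-data
    generators emulating serial-dilution titration designs so every
    estimator can be validated by parameter recovery, and a monoisotopic
    mass utility for verifying tracer identity from molecular formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
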