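Package: solvkb
Title: Minimum-Distance Distribution Functions, Kirkwood-Buff Integrals and
    Preferential Solvation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Solvation-structure analysis for solute-solvent ensembles in
    periodic orthorhombic boxes. Computes minimum-distance distribution
    functions (MDDFs) against an ideal-gas random-insertion reference,
    Kirkwood-Buff integrals from cumulative minimum-distance counts,
    preferential interaction and hydration parameters for cosolvent
    mixtures, atom-group decompositions of MDDFs and per-residue density
    maps. Also provides alpha-helix assignment from Kabsch-Sander
    hydrogen-bond energies, geometric hydrogen-bond counting, block
    averaging and autocorrelation convergence diagnostics for correlated
    time series, and replica exchange with solute tempering (REST2)
    scaling arithmetic. Includes seeded synthetic ensemble generators
    (ideal gas, hard wall, square well) with analytically known
    distribution functions for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
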