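Package: micellr
Title: Micellization Analysis for Lipopeptide Surfactants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantitative analysis of lipopeptide (peptide amphiphile)
    self-assembly in aqueous solution. Estimates the critical micelle
    concentration (CMC) from titration series (surface tension,
    conductivity, fluorescence probe ratios, UV/vis peak position) by
    continuity-constrained two-segment regression with bootstrap
    uncertainty; converts pre-CMC surface-tension slopes into surface
    excess, area per molecule and a surface-derived micelle association
    number via the Gibbs adsorption isotherm; models absolute-scale
    small-angle X-ray scattering (SAXS) from micelles with a core-shell
    sphere form factor, generalized Gaussian-coil monomer term and
    Percus-Yevick hard-sphere structure factor; determines micelle molar
    mass and association number from absolute forward scattering with a
    Tanford chain-volume contrast model; and reduces molecular-dynamics
    observable traces (SASA, radius of gyration, RMSD) to an aggregation
    propensity statistic. Seeded synthetic-data generators with planted
    ground truth emulate all input classes for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    minpack.lm,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
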