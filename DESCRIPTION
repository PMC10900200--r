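Package: glycobalance
Title: Kinetic and Thermodynamic Analysis of In Situ Enamine Molecular Balances
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying weak aromatic interactions (CH/pi,
    cation/pi, anion/pi) with dynamic covalent molecular balances formed in
    situ as Z/E enamine pairs. Simulates the three-reaction mass-action
    network of enamine formation, fits exponential models to Z/E
    concentration-ratio curves to extract equilibrium constants and initial
    flux ratios, converts equilibrium constants to interaction free energies
    with a tiered error model and quadrature error propagation, regresses
    charge and polarization contributions against solvent hydrogen-bonding
    parameters, and generates seeded synthetic HSQC-integral time series for
    validation of the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
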