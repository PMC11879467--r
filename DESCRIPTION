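Package: gibkin
Title: Threshold Analysis and Statistical Kinetics for Gas-Phase Ion-Molecule Reactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for guided-ion-beam studies of ion-molecule
    chemistry, built around the crosslinking reactions of oxidized
    9-methylguanine cations with methylamine. Implements lab-to-center-of-mass
    kinematics, Langevin/Su-Chesnavich capture and orientation-averaged
    hard-sphere collision cross sections, Beer-Lambert absolute cross
    sections, the modified line-of-centers threshold law with Monte Carlo
    convolution over beam energy spread, Doppler broadening, Boltzmann
    internal energies and kinetic shift, threshold-energy fitting with
    uncertainty estimation, Beyer-Swinehart state counting and RRKM rate
    constants with orbiting transition states, Wigner tunneling factors,
    kinetic isotope effects, spin-projected diradical energetics, and
    gas-phase thermochemical cycles, together with synthetic-data generators
    and a reproducible pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
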