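Package: nanobile
Title: Lattice Simulation of Membrane Nanodomains and Biliary Lipid
    Secretion
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Kinetic lattice Monte Carlo model of the exoplasmic leaflet
    of the hepatocyte canalicular membrane. Three lipid species
    (cholesterol, phosphatidylcholine, sphingomyelin) occupy a periodic
    triangular lattice; each site additionally carries a liquid-ordered or
    liquid-disordered state. The system evolves by alternating Gillespie
    kinetic Monte Carlo over neighbor swaps (driven by pairwise
    interaction energies) with Metropolis relaxation of the ordering
    energy, producing transient Lo/Ld nanodomains. Downstream analyses
    cover phase classification, phase-restricted mean squared
    displacement and diffusion coefficients, extraction of bile
    salt-soluble hexagonal membrane patches (extractable membrane
    fraction, lipid secretion rate, bile composition), composition scans,
    and calibration of the energy parameters against diffusion and phase
    measurements via a constrained hypercube-refinement search.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
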