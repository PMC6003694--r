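Package: chromkmc
Title: Coarse-Grained Kinetic Monte Carlo Simulation of Chromatin on a Lattice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kinetic Monte Carlo simulation of chromatin modelled as a
    semi-flexible self-avoiding polymer with stored length on a face-centred
    cubic lattice, together with an entanglement-preserving coarse-graining
    calculus and an epigenomic block-copolymer decoration.  The package
    derives coarse-grained lattice parameters (bond length, Kuhn length,
    bending rigidity) that conserve the chromatin volumic density and the
    entanglement ratio L/Le across resolutions, simulates chain dynamics with
    Metropolis kinetics, and measures Hi-C-style observables: monomer and
    centre-of-mass mean squared displacements, mean squared internal
    distances, contact probability curves and contact maps, intra- versus
    inter-state contact statistics, and pair-contact kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
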