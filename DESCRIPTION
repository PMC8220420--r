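Package: allokin
Title: Nucleotide-Binding Kinetics and Hydrogen-Bond Communication
    Networks for Tandem-Cassette Helicases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying intramolecular communication in the
    two-cassette spliceosomal RNA helicase Brr2 and similar tandem-cassette
    enzymes. One arm simulates and analyses pre-steady-state stopped-flow
    fluorescence experiments: closed-form and mass-action models of
    reversible one- and two-site nucleotide binding, single- and
    double-exponential trace fitting, linear regression of apparent rates
    against ligand concentration, phase-to-cassette assignment, and
    derivation of equilibrium dissociation constants with propagated
    uncertainties and fold-ratio tables. The other arm analyses molecular
    dynamics trajectories: geometric hydrogen-bond detection, residue-pair
    occupancy matrices, weighted communication graphs with -ln(probability)
    edge costs and zero-cost covalent edges, deterministic k-shortest
    loopless paths between nucleotide-binding pockets, interface-crossing
    statistics, block-averaged RMSF, dynamic cross-correlation and
    pocket-width measures. Synthetic-data generators reproduce the
    experimental designs at desk scale so every stage is testable without
    instrument data or long trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    deSolve,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
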