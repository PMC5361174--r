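Package: voroshell
Title: Voronoi Solvation-Shell Analysis for Molecular Simulation Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameter-free analysis of solvation structure around a single
    solute in periodic molecular-simulation trajectories. Space is decomposed
    by a periodic Voronoi tessellation of atomic sites merged into molecular
    cells; solvation shells are graph distances from the solute over the
    face-sharing neighbor graph. On top of the shell assignment the package
    computes shell-decomposed radial distribution functions, running
    Kirkwood-Buff integrals, cumulative and excess coordination numbers,
    per-shell concentrations and solvation free energies, residence-time
    autocorrelation functions with bi-exponential mean residence times,
    per-molecule solute-solvent Coulomb and Lennard-Jones interaction
    energies, and geometric hydrogen-bond counts. A synthetic-configuration
    generator (ideal gas, lattices, surface-enriched solvents, stochastic
    shell-exchange dynamics, planar solutes) provides ground-truth fixtures
    for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
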