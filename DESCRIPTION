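Package: nucleohns
Title: Coarse-Grained Simulation of Chromosome Compaction by H-NS and Crowders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Langevin-dynamics simulation and analysis of a chromosome-like
    ring polymer interacting with patchy H-NS dimers (mobile cross-linking
    binders) and spherical macromolecular crowders in a periodic box.
    Provides the bead-spring model (truncated-shifted Lennard-Jones pair
    potentials, FENE ring bonds, harmonic patch-core geometry of the H-NS
    triplex), a velocity-Verlet integrator with a Langevin thermostat and
    neighbour lists, system builders for arbitrary chain lengths, crowder
    volume fractions and binder counts, and an observables pipeline:
    compaction ratio Rg/Rg0, binding probability and its dangling versus
    bridging decomposition, genomic bridge spans, and H-NS cluster-size
    statistics under periodic boundary conditions. Trajectories are read and
    written as extended XYZ or a LAMMPS-dump text dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
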