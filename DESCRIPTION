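Package: redoxfold
Title: Reactive Coarse-Grained Molecular Dynamics for Oxidative Peptide Folding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained coarse-grained Langevin dynamics engine with a
    perturbation-free reactive protocol for disulfide-bond formation during
    peptide folding. Reactive cysteine sulfurs have their pairwise
    Lennard-Jones term masked so they can diffuse within a capture radius;
    close encounters are detected on stored frames, optionally passed through
    a rejection-sampling reactivity gate, the trajectory is rewound bitwise to
    the crossing frame, and the disulfide geometry is installed by ramping
    harmonic distance/angle/dihedral restraints before the pair is converted
    to a permanently bonded topology. Includes seeded generators of
    guanylin-like test chains, trajectory analysis (disulfide isomer
    classification, kinetic footprints, radius of gyration, ensemble RMSD with
    rigid-body superposition, NOE restraint violation scoring with r^-6
    averaging of equivalent protons), and plain-text structure, trajectory,
    configuration and event-log formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
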