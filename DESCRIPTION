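Package: sumdr
Title: Supervised Molecular Dynamics Sampling and Trajectory Analysis on Toy Systems
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Adaptive-sampling molecular dynamics machinery for ligand
    binding and unbinding studies, exercised on bundled bead-and-potential
    toy systems. Implements tabu-like supervised MD (SuMD) with linear-fit
    window acceptance, double-metric adaptive unbinding supervision with a
    distance-scheduled window length, RMSD-binned path sampling, and
    well-tempered metadynamics on a distance collective variable, together
    with trajectory-analysis operators: interatomic contacts, geometric
    hydrogen bonds, per-residue interaction persistency over merged
    replicas, Kabsch superposition and RMSD, two-variable interaction
    energy landscapes, and voxelised water-occupancy maps. A Langevin
    (BAOAB) engine for beads in configurable funnel, soft-core repulsion,
    harmonic, and double-well potentials stands in for all-atom MD so the
    whole protocol runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    bio3d,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
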