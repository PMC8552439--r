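Package: msmhdx
Title: Markov State Model Ensemble Analysis and Hydrogen-Exchange
    Protection Factors from Molecular Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes the structural ensemble of a protein monomer from
    multi-trajectory molecular dynamics data. Identifies the slowest
    decorrelating collective modes by integrated variational dimensionality
    reduction (IVAC/tICA) on pairwise alpha-carbon distances, clusters the
    projected data into microstates, estimates and validates a Markov state
    model, coarse-grains it into metastable macro-clusters by Perron cluster
    analysis with populations and equilibrium fluxes, counts per-site backbone
    amide hydrogen bonds to protein acceptors and to water under geometric
    criteria, and turns those counts into per-structure, per-cluster and
    ensemble hydrogen-deuterium exchange protection factors under four models.
    Includes a synthetic trajectory generator driven by a hidden discrete-state
    Markov chain with known geometry and hydrogen-bond ground truth, and
    configurable geometric annotation of elements of conformational disorder.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    yaml
Config/testthat/edition: 3
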