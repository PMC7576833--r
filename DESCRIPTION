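Package: paratopeMSM
Title: Kinetic Characterization of Antibody Paratope States from
    Conformational Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to characterize the conformational states of antibody
    binding sites (paratopes) from conformational-ensemble trajectories.
    Implements backbone-torsion sin/cos featurization of CDR loops,
    time-lagged independent component analysis (tICA), k-means
    microstating, reversible Markov-state model estimation with
    Chapman-Kolmogorov validation, PCCA+ metastable coarse-graining,
    center-of-mass torsion observables for the VH-VL interface angle and
    the Fab elbow angle, average-linkage RMSD clustering of loop
    conformations, canonical-cluster assignment against user-supplied
    median torsions, CDR loop co-occurrence analysis, and synthetic-data
    generators with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
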