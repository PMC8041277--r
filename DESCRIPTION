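Package: memdock
Title: Bilayer-Constrained Rigid Docking of Transmembrane Protein Dimers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body docking engine for preoriented transmembrane protein
    pairs. Conformational ensembles are converted into smooth volumetric
    density maps, maps into triangulated isosurfaces, and ligand poses are
    searched in a bilayer-constrained seven-dimensional space (x/y/z
    translation, precessing rotation axis, rotation angle) by maximising a
    surface-complementarity score with a particle-swarm "kick and reseed"
    optimiser. Positive-score poses are clustered with K-means to select
    ranked representative models, and models are assessed against a reference
    complex with CAPRI-style metrics (fnat, ligand RMSD, interface RMSD) and
    quality tiers. Includes deterministic synthetic toy dimers and jittered
    ensembles so the whole pipeline is testable without molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
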