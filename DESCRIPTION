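Package: restenosim
Title: Lattice-Based Simulation of Neointimal Growth in Stented Arteries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A cell-centred, lattice-based simulator of in-stent restenosis.
    The artery wall is voxelized into a regular 3D grid; stent-induced injury
    is derived by thresholding a per-element minimum-principal-stress field
    (imported from a finite-element mesh or generated synthetically from a
    parametric stent description); smooth muscle cells switch between
    contractile and synthetic phenotypes, migrate by random walk, proliferate
    against a local growth stimulus and produce extracellular matrix, while
    matrix-degrading factors resorb injured tissue and endothelial cells
    re-colonise the denuded lumen surface. Daily metrics (neointimal area per
    slice, lesion volume, cell counts, population doublings) are returned as
    tidy tibbles, with VTK and CSV export for snapshots and time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    readr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
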