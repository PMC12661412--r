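Package: idkit
Title: Nanodosimetric Ionization-Detail Databases and Cluster-Dose Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for computing nanodosimetric ionization-detail quantities
    for ion-beam radiotherapy research. Scores ionization cluster size
    distributions in a dense lattice of DNA-segment-sized cylindrical
    sampling volumes, builds lookup databases of ionization parameters
    (cumulative cluster frequencies F_k) on adaptively spaced energy grids,
    converts condensed-history step logs into voxel-averaged ionization
    parameters and cluster dose through a substep decomposition aligned
    with the database energies, and relates cluster dose to clonogenic cell
    survival through linear-quadratic fits to identify the ionization
    parameter definition most closely associated with survival. Includes a
    synthetic track generator and a one-dimensional depth-dose phantom so
    the full pipeline runs without an external Monte Carlo engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
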