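Package: gridfields3d
Title: Plane-Dependent Simulation of 3D Grid-Cell Firing Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates three-dimensional grid-cell firing with a training-free,
    weight-variable complex recurrent network driven by screw-axis-decomposed
    self-motion under uncertain perception of reference planes. Provides
    bounded random-walk, manifold and mode-switching trajectory generators,
    von Mises-Fisher directional sampling, FCC/HCP/columnar/random prototype
    lattices, and a metrics suite for 3D field structure: spatial information
    and sparsity with shuffle Z-scores, mean-shift field detection and
    inter-field distances, 3D spatial autocorrelograms, oblique-slice grid
    score maps, FCC/HCP/COL structure scores, and modified radial
    autocorrelation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
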