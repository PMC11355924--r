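Package: trabnet
Title: Curvature-Based Analysis of Trabecular Microstructures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing trabecular-bone-like voxel microstructures
    through their surface curvature fields. Generates synthetic trabecular
    representative volume elements and analytic fixtures, extracts triangle
    surface meshes and per-vertex principal, Gaussian and mean curvatures,
    builds 2D curvature projection images, computes global histomorphometric
    parameters (BV/TV, BS, Tb.Th, SMI, DA, Conn.D), decomposes structures
    into individual plates and rods with geometric summaries, homogenizes
    the apparent elastic stiffness tensor by voxel-based finite elements
    under kinematic uniform boundary conditions, and trains a convolutional
    neural network that regresses all of these quantities from the
    curvature projection images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
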