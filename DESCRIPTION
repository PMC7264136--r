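Package: MARedge
Title: Auto-Edge Counting for Quantifying Metal Artifact Reduction in CBCT
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the efficacy of metal artifact reduction (MAR)
    reconstruction in cone-beam computed tomography (CBCT) image stacks by
    automatic edge counting. Implements a Canny edge detector extended with an
    up-front impulse-noise removal stage, counts edges as 8-connected components
    of the binary edge image ("a continuous line with no breaks"), and derives
    the edge reduction ratio between paired acquisitions taken with and without
    the MAR option. A statistical layer provides Shapiro-Wilk normality
    screening, Welch's one-way ANOVA with the Games-Howell post hoc test across
    prosthesis types, and Welch t-tests across scan modes (voxel size, tube
    voltage). A synthetic arch-phantom simulator generates matched MAR-off/MAR-on
    stacks with radial streak artifacts and known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'edge_detect.R'
    'artifact_metrics.R'
    'image_io.R'
    'phantom_sim.R'
    'stats_suite.R'
    'cli.R'
    'read_formats.R'
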