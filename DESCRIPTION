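Package: pelletmorph
Title: Quantitative Macro- and Micromorphology of Filamentous Fungal Pellets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying the morphology of filamentous fungal
    pellet populations from submerged cultivation. Provides a seeded
    synthetic-data generator (2D pellet micrographs, 3D pellet voxel
    volumes, and regression datasets with known ground truth), a
    marker-controlled watershed segmentation pipeline for 2D micrographs
    built on morphological reconstruction filtering, population
    heterogeneity statistics (median, interquartile range, number-density
    histograms, and the distribution-free overlap coefficient OVL),
    multiple linear regression of median pellet diameter on cultivation
    parameters with assumption diagnostics and variance inflation factors,
    and 3D internal-architecture analysis (radial solid-fraction profiles,
    density-based spore-core clustering, pellet core classification, and
    hyphal skeleton metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
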