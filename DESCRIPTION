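Package: strataconn
Title: Structural and Functional Connectivity of Stratified Urban
    Greenspace
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Stratifies urban vegetation into grass, shrub and tree layers
    from NDVI imagery combined with voxelized fractional canopy cover, and
    quantifies how the vertical structure of greenspace changes landscape
    connectivity. Computes per-layer structural metrics (landscape
    proportion, small patch density, largest patch index, and the
    connectivity / landscape division index), and models functional
    connectivity as the connectivity index under incremental Euclidean
    buffering of vegetated surfaces, including 2D-versus-strata bias
    curves and dispersal threshold distances. A seeded synthetic townscape
    generator emulates reflectance and voxel canopy inputs with
    controllable cover, fragmentation and urban-form archetypes so the
    whole pipeline runs without airborne survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
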