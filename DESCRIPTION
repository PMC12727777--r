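Package: microdomain3d
Title: Quantitative 3D Geometry of Organelle Contact Sites in Volume
    Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Morphometry of endoplasmic-reticulum/plasma-membrane junctions
    and mitochondria-associated membranes (MAM) from segmented volume electron
    microscopy label stacks. Reads multi-page TIFF or HDF5 label volumes with
    anisotropic voxel spacing, extracts triangle meshes by marching cubes,
    crops spherical microdomains around caveola seed points, computes the
    average surface distance (ASD) between plasma-membrane and ER meshes,
    detects sub-threshold ER-PM proximity events and sub-20 nm ER-mitochondria
    contact patches, and aggregates per-sphere metrics (mean, median, SD,
    coefficient of variation) with a MAM-positive-only inclusion rule. A
    synthetic phantom generator with analytic ground truth emulates the
    peripheral-ER architectures of smooth muscle cells, interstitial cells of
    Cajal and PDGFRA-positive cells so the whole pipeline is testable without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    RANN,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
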