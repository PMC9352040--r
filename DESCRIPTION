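Package: canalmorph
Title: Morphometry of Branching Canal Networks from 3D Micro-CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative 3D morphometry of tubular canal networks imaged by
    X-ray micro-computed tomography, motivated by resin endocasts of the
    jellyfish gastrovascular system. Provides Otsu segmentation of grayscale
    volumes, connectivity-preserving Gaussian smoothing, an exact
    maximal-inscribed-sphere local-thickness transform, homotopy-preserving
    3D thinning skeletonization with terminal-branch pruning, skeleton-graph
    decomposition into branches, junctions and endpoints with per-branch
    length, Euclidean distance and tortuosity, per-substructure volume and
    opening counts, and whole-organism extrapolation. A synthetic phantom
    generator produces voxelized branching-tube networks with exact ground
    truth so every pipeline stage is testable without real scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    tiff,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus
Config/testthat/edition: 3
RoxygenNote: 7.3.3
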