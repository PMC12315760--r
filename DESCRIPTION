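Package: vascmrf
Title: MR Vascular Fingerprinting Simulation and Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates voxel-scale microvascular magnetic resonance
    fingerprints and reconstructs microvascular parameter maps from them.
    Provides generators for synthetic vascular voxel geometries (2D disks,
    isotropically oriented 3D cylinders, stochastic branching networks),
    a Fourier dipole-kernel susceptibility field solver, an isochromat
    simulator for gradient-echo sampling of the free induction decay and
    spin echo (GESFIDSE) with water diffusion, scrambled Sobol sampling of
    the (SO2, T2) parameter space, dictionary construction for pre/post
    contrast-agent fingerprints, and two reconstruction routes: exhaustive
    dictionary matching (DBM) and Bayesian inverse regression by a Gaussian
    locally linear mapping (DBL). Includes phantom generation, region-of-
    interest statistics, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    RNifti,
    EBImage,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
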