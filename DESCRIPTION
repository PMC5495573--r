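Package: protoconn
Title: Correlation-Based Mapping of Hierarchical and Retinotopic
    Proto-Organization in Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying the proto-organization of the primate visual
    system from resting-state and phase-encoded fMRI time series. Implements
    temporal preprocessing of rest scans (despiking, band-pass filtering,
    polynomial detrending, nuisance regression, mean normalization),
    size-balanced seed correlations between retinotopic areas within and
    across hemispheres, second-order areal correlation profiles, homotopic/
    adjacent/distal and dorsal-ventral quadrant groupings, V1
    eccentricity-band correlation curves with Gaussian peak fitting,
    community and hierarchy analysis of areal correlation networks
    (leading-eigenvector modularity, Ward clustering with inconsistency
    cuts, Kruskal-stress multidimensional scaling), a smoothed-noise
    instrumentation null, and Fourier analysis of phase-encoded retinotopic
    and spatial-frequency mapping designs. A synthetic two-hemisphere data
    generator with planted homotopic coupling, hierarchical community
    structure, and eccentricity gradients makes the whole pipeline testable
    without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    RNifti,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
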