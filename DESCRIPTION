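Package: larvaflow
Title: Wave-Driven Boundary-Layer Flow and Coral Larval Settlement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how millimeter-scale substrate topography
    modifies wave-driven oscillatory boundary-layer flow and thereby
    facilitates the settlement of slow-swimming coral larvae. Provides
    synthetic, divergence-free oscillatory flow fields over flat and ridged
    substrates (an exact oscillatory Stokes layer and a streamfunction-based
    recirculating cavity model), tracer advection and synthetic particle
    imagery, particle tracking velocimetry (detection, linking, phase-averaged
    gridding), Q-criterion vortex identification and settling-window
    statistics, an agent-based simulation of ellipsoidal swimmers with
    Jeffery rotation in shear, and the settlement statistics (arcsine-square-
    root transform, ANOVA with Tukey HSD, settlement-location geometry).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    broom,
    readr,
    jsonlite,
    yaml,
    pracma,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr
Config/testthat/edition: 3
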