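Package: hulatwist
Title: Trajectory-Ensemble Analysis of Bathy Phytochrome Photoactivation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ensembles of chromophore trajectories from
    photoreceptor simulations, built around the photoactivation of bathy
    bacteriophytochromes. Computes signed bilin dihedrals with Z/E-s/a
    stereochemistry codes, detects hula-twist photoisomerization events with
    rotation sense, fits right-censored exponential-mixture decay kinetics and
    photoisomerization quantum yields, clusters binding-pocket distance
    geometry (PCA + Ward), classifies photoproduct intermediates from
    hydrogen-bond patterns and dihedral windows, measures helix-spine tilt,
    and estimates proton-transfer free energies on a one-dimensional model
    surface with an adaptive-bias (well-tempered kernel) sampler. A synthetic
    ensemble generator reproduces the statistical structure these analyses
    assume, so every stage is testable without electronic-structure or
    molecular-dynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    mclust,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
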