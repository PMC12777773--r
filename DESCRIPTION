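Package: lumenflow
Title: Small-Intestinal Motility Simulation and Luminal Drug Transport
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates fed-state segmentation and fasted-state peristalsis of
    the small intestine as prescribed moving-wall kinematics with exact
    luminal volume conservation, solves the transient axisymmetric
    incompressible Navier-Stokes equations on the deforming lumen for
    Newtonian and shear-thinning power-law fluids, and couples a two-species
    advection-diffusion module for a model macromolecule (insulin) and a
    permeation enhancer (sodium caprate, C10). Computes epithelial delivery
    metrics (near-wall mole percentages, escape fractions, wall surface
    concentrations, wall shear stress), a colocalisation score for
    macromolecule/enhancer co-delivery, and provides a factorial sweep
    pipeline with rank-based comparisons, K-means clustering, and
    gradient-boosted regression with SHAP feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
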