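Package: epigrowth
Title: Continuum Models of Epithelial Tissue Growth and Collision
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for simulating and calibrating continuum models of
    expanding and colliding epithelial monolayers. Provides conservative,
    positivity-preserving finite-volume solvers for the Fisher-KPP
    (linear diffusion) and Porous-Fisher (population-pressure driven,
    degenerate diffusion) reaction-diffusion equations on 2D Cartesian
    and radially symmetric 1D grids, including their multi-species
    cross-diffusion extensions with a shared pressure; a synthetic
    observation generator emulating voxelised cell-density measurements
    with additive Gaussian noise; maximum-likelihood and adaptive
    Metropolis-Hastings MCMC parameter inference with log-uniform priors
    and Gelman-Rubin diagnostics; and quantification of tissue-tissue
    collisions (interface tracking, boundary displacement, segregation
    indices and displacement scaling laws).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    MASS
Config/testthat/edition: 3
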