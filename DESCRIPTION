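Package: awhperm
Title: Accelerated Weight Histogram Sampling and Membrane Permeability on
    Langevin Model Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adaptive-bias free-energy sampling with the accelerated weight
    histogram (AWH) method on one- or two-dimensional (spatial x alchemical)
    reaction coordinates, applied to synthetic lambda-coupled membrane
    landscapes integrated by Langevin dynamics. Includes expanded-ensemble
    Monte Carlo moves over an alchemical decoupling coordinate with soft-core
    coupling, multi-walker shared-bias sampling with initial-stage covering
    logic, position-dependent diffusion profiles from the friction metric
    (bias-force autocorrelation), and the inhomogeneous solubility-diffusion
    permeability pipeline: solvent calibration of the potential of mean force,
    the resistance integral, bilayer-count scaling, and log10 permeability
    coefficients in cm/h with propagated uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
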