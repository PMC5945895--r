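Package: netcourse
Title: Spatiotemporal Disease-Course Models for Signals on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a nonlinear mixed-effects model of disease progression for
    longitudinal signals distributed on a graph, such as cortical thickness
    measured on a mesh of the brain surface. Each node follows a straight-line
    population trajectory; individuals differ by a log-normal acceleration
    factor, a Gaussian time shift, and a low-rank space shift orthogonal to
    the population velocity. Spatial smoothness is imposed by Gaussian-kernel
    interpolation of position and velocity fields from a subset of control
    nodes. Parameters are estimated by maximum likelihood with the MCMC-SAEM
    algorithm (Metropolis-within-Gibbs simulation, Robbins-Monro averaging of
    sufficient statistics, closed-form maximization). Includes tools for graph
    construction and mesh subsampling, synthetic-data generation with known
    ground truth, personalization of fitted models to new subjects, and
    reconstruction-error reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
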