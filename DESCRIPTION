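Package: navlnp
Title: Reverse-Correlation Analysis of Larval Navigation with
    Linear-Nonlinear-Poisson Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for behavioural reverse correlation of Drosophila larva
    navigation. Generates Brownian and square-wave light-intensity stimuli,
    simulates a virtual larva whose runs, turns and head sweeps are driven by a
    Linear-Nonlinear-Poisson (LNP) cascade, and estimates the model components
    back from event data: turn-triggered averages, smoothed convolution
    kernels, ratio-of-Gaussians nonlinearities, and step-response predictions.
    For two-channel (odor plus light) experiments it fits the
    independent-pathways and early-linear-combination integration models by
    maximum likelihood, compares them by AIC, rotates filtered and raw
    coordinates, estimates Kullback-Leibler divergences by k-nearest-neighbour
    and Gaussian-analytic methods, and runs a quadrant-wise attention analysis
    of head-sweep acceptance.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
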