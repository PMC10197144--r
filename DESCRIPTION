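Package: edofpupil
Title: Genetic-Algorithm Design of Binary Pupil Phase Masks for Extended
    Depth-of-Field Miniscope Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs binary (0/pi) diffractive pupil phase masks that extend
    the depth of field of miniature one-photon fluorescence microscopes built
    around high-NA gradient refractive index (GRIN) objectives. Implements a
    Fourier-optics forward model with angular-spectrum defocus, Seidel
    spherical aberration of the GRIN lens and scattering-induced intensity
    decay; a queen-bee (elitist) genetic algorithm that optimizes axicon,
    defocus and spherical-aberration basis coefficients against a
    depth-coverage fitness; depth-of-field and resolution characterization of
    simulated intensity stacks; a Laplacian-of-Gaussian postprocessing filter
    with particle extraction; and a synthetic fluorescent-bead phantom
    generator with a Lorenz-Mie scattering-length calculator that replaces
    bench experiments with seeded simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    igraph,
    withr,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
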