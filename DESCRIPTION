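Package: frontscape
Title: Population Range Expansions in Heterogeneous Two-Dimensional Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying how finite-sized obstacles and hotspots,
    randomly placed in a two-dimensional habitat, shape the speed and shape
    of expanding population fronts. Provides a stochastic individual-based
    birth-coagulation-diffusion simulator, a fast-marching solver for the
    Eikonal (least-time) equation on rasterized landscapes, closed-form
    least-time solutions for single features (kink healing, hotspot bulges,
    Snell refraction), an event-based scattering construction of fronts, and
    ensemble experiments for front speed as a function of feature density,
    shape and strength, including continuum-percolation blockage of
    obstacle landscapes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
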