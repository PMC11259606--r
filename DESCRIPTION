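Package: triadicperc
Title: Triadic Percolation and Dynamical Topological Patterns on Spatial Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for triadic percolation on spatially
    embedded higher-order networks. Generates Waxman-type structural networks and
    signed spatial regulatory (triadic) interactions on a 2D torus, iterates the
    two-step percolation dynamics in which regulator nodes switch structural links
    on and off, and characterises the resulting spatio-temporal patterns of the
    giant component: Vietoris-Rips persistent homology with Wasserstein
    nearest-template classification into cluster/octopus/stripe classes,
    two-dimensional permutation entropy and LMC statistical complexity on a
    density grid, and temporal statistics (pattern overlap, return probability,
    symbolic entropy rate, circular barycenter). Includes an experiment pipeline
    for phase-diagram sweeps over the link-retention probability and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
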