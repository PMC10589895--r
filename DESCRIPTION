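Package: gridtorus
Title: Grid-Cell Remapping and Toroidal Population Analysis in Trained
    Path-Integration Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for studying how recurrent
    networks trained to path integrate across globally remapping place-cell
    environments organise their units. Provides a 2D foraging random-walk
    simulator, difference-of-softmax place-cell encoding and top-3
    center-of-mass decoding, a continuous-attractor style recurrent network
    trained by backpropagation through time (RcppArmadillo core), unit
    pruning experiments, an ideal grid-cell module generator with coherent
    and incoherent phase/orientation remapping scenarios, single-cell
    spatial statistics (ratemaps, spatial autocorrelograms, grid score,
    grid spacing, phase and orientation shifts), rotational-symmetry
    clustering of unit types, and Vietoris-Rips persistent homology for
    detecting toroidal population manifolds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
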