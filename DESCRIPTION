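Package: mtubesim
Title: Generative Modeling of Microtubule Distributions with Indirect
    Parameter Estimation from 2D Fluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates three-dimensional microtubule distributions
    conditioned on cell and nuclear geometry using a centrosome-nucleated
    growth model with Erlang-distributed filament lengths and angular
    constraints on curvature.  Builds approximate 3D cell and nuclear
    morphologies from single 2D confocal slices, renders synthetic
    fluorescence volumes through a parametric confocal point spread
    function, and recovers model parameters (number of microtubules, mean
    length, collinearity, cell height) for a query image by matching
    texture, edge and intensity features against a per-cell library of
    synthetic images.  Includes the downstream multivariate statistics
    used to compare microtubule parameters across cell populations
    (Hotelling's T2, Box's M, subsampled pairwise testing with Bonferroni
    correction, hierarchical clustering, PCA) and a fully synthetic
    validation workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    ape,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
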