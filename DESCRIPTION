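Package: molforge
Title: Zero-Shot 3D Molecular Generation with Local-Environment Similarity Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates three-dimensional molecular structures without any
    trained model by annealed maximisation of the similarity between local
    atomic environments and a small bank of reference environments. Provides
    rotation- and permutation-invariant many-body descriptors with analytic
    gradients, a radial-basis-function similarity energy and force, Gaussian
    and point-cloud shape priors, an annealed stochastic sampler interleaved
    with element-swapping particle-swarm optimisation, valence-based
    hydrogenation and geometry refinement, validity metrics, similarity-energy
    landscape scans, and guidance utilities for external score models.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    jsonlite,
    yaml,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    ChemmineR
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
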