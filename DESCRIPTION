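Package: nips
Title: Network Inference from Partial State Observations of Coupled
    Dynamical Systems
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs directed network connectivity when only a single
    scalar observable per node is measured. Each node of the network is
    embedded individually with forced time-delay coordinates, the coupling
    inputs from the remaining nodes being treated as known external forcing,
    and the observable's dynamics are fitted by additive basis-function
    regression (a multivariate polynomial in the node's own delayed
    observations plus one univariate polynomial per candidate source node)
    solved by plain least squares.  The squared coupling-block coefficients
    rank candidate edges.  Includes benchmark network generators and
    simulators (nickel electrodissolution oscillators, Rulkov map neurons,
    circadian clock cells, Roessler oscillators), delay selection by average
    mutual information, a whole-network embedding variant for coupling
    through unobserved states, and an evaluation suite (ROC/AUROC, Otsu
    thresholding, weight-recovery correlation, Kuramoto synchronization
    index, data-length sweeps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    grDevices,
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
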