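Package: spongenet
Title: Host-Microbe Network Structure and Sparse Lotka-Volterra
    Interaction Inference for Sponge Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing large replicated host-microbiome surveys:
    reading and filtering OTU count tables (mothur '.shared' dialect and
    plain TSV), community richness and diversity metrics, construction of
    host-OTU bipartite networks with truncated power-law and exponential
    degree-distribution fits, specialist/generalist/opportunist
    classification, core-microbiome extraction, Bayesian sparse
    Lotka-Volterra inference of microbe-microbe interactions with Gibbs
    variable selection, stationary variance decomposition into density
    dependence, interactions and stochasticity, representative interaction
    networks, sponge-specific sequence-cluster assignment, and
    phylogenetic-signal statistics.  A synthetic-data module generates
    community tables, replicate series, similarity hit tables and trees
    with the statistical structure the analyses assume, so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    vegan,
    igraph,
    jsonlite,
    minpack.lm,
    withr,
    coda,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags,
    picante,
    optparse,
    biomformat
Config/testthat/edition: 3
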