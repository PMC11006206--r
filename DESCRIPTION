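Package: fibersync
Title: Fibration Symmetries and Cluster Synchronization in Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for analyzing symmetry-driven cluster synchronization in
    small neuronal circuits. Partitions directed and undirected weighted
    multigraphs into fibers (minimal balanced colorings) and orbits
    (automorphism classes), decomposes circuits into fiber building blocks
    with branching-ratio/trail-count fiber numbers, simulates admissible
    in-degree coupled neuron dynamics (gap-junction and two chemical-synapse
    models) under external stimuli, analyzes equilibrium stability through
    Jacobian eigenvalue sweeps, and quantifies synchrony with Gaussian-kernel
    (LoS) and phase-locking (PLV) metrics. Includes a planted-symmetry
    synthetic network generator so every analysis is reproducible without
    external connectome data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
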