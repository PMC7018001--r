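Package: modcom
Title: Multi-Community Detection by Modularity Maximization as a QUBO
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects communities in undirected, optionally weighted networks by
    maximizing Newman modularity, recast as a quadratic unconstrained binary
    optimization (QUBO) problem with a k-concurrent one-hot ("logical
    super-node") encoding and solved by a seeded classical simulated-annealing
    sampler. Includes the modularity-matrix construction with thresholding for
    problem sparsification, an exhaustive solver and brute-force set-partition
    oracle for small instances, a planted-partition generator for validation,
    bundled classic benchmark graphs (Zachary karate club, Les Miserables),
    and a pluggable sampler contract for external QUBO backends.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
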