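Package: annet
Title: Anatomical Network Analysis of Musculoskeletal Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for anatomical network analysis (AnNA) of musculoskeletal
    systems. Builds undirected, unweighted networks of bones and muscles from
    binary adjacency matrices, computes the standard topological parameters
    (nodes, links, density, clustering coefficient, characteristic path
    length, degree heterogeneity), detects connectivity modules with a
    random-walk (walktrap) community algorithm and scores them with
    Newman-Girvan modularity, a jackknife standard error and per-module
    Wilcoxon rank-sum tests, and relates network parameters across species to
    a time-calibrated phylogeny via Pagel's lambda, Blomberg's K and
    maximum-likelihood ancestral state reconstruction with phenogram export.
    Includes generators for limb-like modular networks with planted ground
    truth, pure-birth trees and Brownian-motion trait evolution so the whole
    pipeline can be exercised on synthetic data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
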