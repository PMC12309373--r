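Package: fishnet
Title: Cluster-Anchored Over-Representation Analysis of Dose-Response
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline, file-driven workflow for the functional
    interpretation of deregulated gene lists from dose-response
    transcriptomics. Deregulated genes are clustered on a
    confidence-thresholded protein-protein interaction network with an
    internal Markov Cluster (MCL) implementation, clusters are
    characterised by hypergeometric over-representation analysis against
    user-supplied gene-set collections with false-discovery-rate control
    and size filters, clusters sharing enriched functions are merged,
    isolated ("lonely") genes are rescued into clusters through shared
    annotations, and every final cluster is summarised with benchmark-dose
    sensitivity metrics. A deterministic synthetic-fixture generator with
    planted ground truth makes every stage testable without network
    access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
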