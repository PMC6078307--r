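Package: bgmnet
Title: Tripartite Brain-Gut-Metabolite Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds subject-level functional and anatomical brain connectomes
    from region-wise time series and fiber counts, computes weighted
    graph-centrality metrics (degree strength, shortest-path betweenness) for
    extended-reward-network regions, runs covariate-adjusted Spearman
    correlations across metabolite, clinical, and brain-metric data blocks
    with Benjamini-Hochberg false-discovery control, and assembles the
    resulting tripartite association network with direct and indirect
    (brain-mediated) effect classification. Includes a latent-factor cohort
    simulator with plantable cross-block correlations so the whole pipeline
    is testable end to end, and a bundled reference association table from a
    published 63-subject cohort for structural reproduction checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    igraph,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
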