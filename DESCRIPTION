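Package: dfcverse
Title: Dynamic Functional Connectivity, Graph Metrics, and Multiverse Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of static, continuously varying, and state-based
    functional connectivity from multivariate time series (sliding-window and
    tapered correlation, multiplication of temporal derivatives, jackknife
    correlation, edge time series, spatial distance, flexible least squares,
    phase synchronization, leading eigenvector dynamics, co-activation
    patterns, Gaussian hidden Markov models, k-means state clustering);
    graph-theoretic analysis of (thresholded) connectivity matrices (degree,
    clustering, path length, global and local efficiency, matching index,
    modularity, Louvain community detection); and a multiverse engine that
    expands user-declared forking paths into runnable per-universe analysis
    scripts summarized by specification curves. Includes synthetic-data
    generators with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    signal,
    igraph,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
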