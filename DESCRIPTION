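Package: roinet
Title: ROI-Level Resting-State Connectomics with Graph Topology and Group Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for region-of-interest (ROI) resting-state
    connectomics. Starting from per-subject ROI time-series tables, the package
    performs temporal denoising (motion-outlier detection and scrubbing,
    nuisance regression, linear detrending and band-pass filtering), computes
    functional (bivariate correlation) and effective-like (bivariate
    regression) connectivity matrices with Fisher z-transformation, derives
    binary graphs by absolute thresholding and seven node-level topology
    metrics (degree, cost, betweenness centrality, average path length, global
    efficiency, local efficiency, clustering coefficient), and compares two
    groups edge-wise and node-wise with pooled two-sample t-tests under
    Benjamini-Hochberg false-discovery-rate control. A deterministic synthetic
    cohort generator with block-structured ROI covariance and planted group
    differences exercises the whole pipeline without imaging data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
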