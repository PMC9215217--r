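Package: oceanmover
Title: Optimal Transport Distances for Gridded Ocean Scalar Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact 2-Wasserstein (earth mover's) distances between normalized
    geospatial scalar fields such as ocean chlorophyll maps and depth
    profiles, using great-circle base costs on the sphere and absolute depth
    differences in the vertical. Solves the transportation linear program
    with a network (transportation) simplex, returns the optimal transport
    plan for visualization, and provides the downstream analyses built on
    it: pairwise distance matrices with classical multidimensional scaling,
    seasonal-trend regression of distances on month lags, K-means province
    boundary extraction and comparison, deep-chlorophyll-maximum profile
    analysis, and a synthetic-data generator for testing every stage
    without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    geosphere,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
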