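Package: cossr
Title: Topology-Based Spatial Structure Scores for Well-Based Spatial Omics
Version: 0.1.0
Authors@R:
    person("cossr", "developers", email = "cossr@example.org", role = c("aut", "cre"))
Description: Quantifies spatial structure in well-based spatial omics data
    (Visium-style spatial transcriptomics, mass spectrometry imaging) with a
    per-feature Coefficient of Spatial Structure (CoSS): expression is smoothed
    with a weighted distance-to-measure using idealized lattice network
    distances, inverted into an expression landscape, and summarised by the
    L^p norm of the 0-dimensional persistence barcode of the upper star
    filtration on the well adjacency graph. Includes automatic lattice
    alignment for hexagonal and square arrays, spatially-variable-feature
    calling via the kneedle elbow on the CoSS-rank curve, between-group
    differential spatial structure analysis, readers for common matrix
    dialects, a synthetic data generator with ground truth, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
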