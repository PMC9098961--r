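Package: mcnet
Title: Metabolic Covariance Brain Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Group-level metabolic covariance network analysis for regional
    FDG-PET intensities. Builds inter-regional Pearson correlation networks
    per subject group, binarizes them over a sparsity sweep or by an absolute
    correlation cutoff, computes global and nodal graph-theory parameters
    (characteristic path length, clustering, global and local efficiency,
    betweenness centrality) with small-world indices against degree-preserving
    rewired null graphs, identifies hub regions by the mean-plus-SD
    betweenness rule, compares groups with label-permutation tests and
    Benjamini-Hochberg FDR correction, and quantifies hemispheric asymmetry.
    Includes regional mean-intensity extraction from labelled NIfTI volumes
    and a synthetic-data generator with planted covariance structure, hubs
    and group effects for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    MASS,
    RNifti,
    yaml,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
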