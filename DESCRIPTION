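Package: trajensemble
Title: Ensemble Clustering of Longitudinal Biomarker Trajectories with
    Shape-Respecting Distances
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters irregular, variable-length longitudinal biomarker
    trajectories by profile shape using elastic distances (dynamic time
    warping and discrete Frechet), builds per-marker hierarchical
    clusterings, and aggregates them into a single consensus clustering by
    least-squares ultrametric fitting with a sequential unconstrained
    minimization (SUMT) penalty scheme. Includes simulation harnesses: a
    cylinder-bell-funnel benchmark generator with missing-completely-at-
    random thinning, and a synthetic bivariate CD4/viral-load cohort
    generator with latent progression groups, plus external (adjusted Rand,
    Fowlkes-Mallows, purity) and internal (silhouette, Dunn) cluster
    validity indices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
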