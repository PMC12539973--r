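Package: shaperate
Title: Branch-Specific Evolutionary Rates for High-Density Geometric Morphometric Shape Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phylogenetic comparative analysis of landmark-based shape
    evolution. Implements generalized Procrustes superimposition, region-wise
    shape decomposition, principal component models of species consensus
    shapes, Brownian-motion and multiple-variance Brownian-motion ancestral
    state estimation, generation-time rescaling of time-calibrated
    phylogenies, and branch-specific evolutionary rates measured as excess
    shape change relative to a simulated constant-rate neutral expectation.
    Also provides clade disparity statistics with permutation and exact
    Wilcoxon tests, multivariate Brownian rate (sigma2_mult) comparisons
    across clades and anatomical regions, lambda-fixed phylogenetic allometry
    models, evolutionary rate correlations, a synthetic-data generator for
    the assumed generative model, and a config-driven end-to-end pipeline
    producing tabular reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
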