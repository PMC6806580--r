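Package: riverneutral
Title: Neutral Community Models and Spatial Analysis of Riverine
    Microbial Metacommunities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying stochastic and deterministic assembly of
    riverine microbial plankton communities from sample-by-OTU count tables.
    Implements Sloan's neutral community model (occurrence frequency versus
    metacommunity relative abundance under a beta stationary distribution),
    with nonlinear least-squares estimation of the dispersal parameter Nm,
    bootstrap confidence intervals, and partitioning of taxa into above-,
    within-, and below-prediction fractions; rarity classification of OTUs
    into six abundance categories; alpha diversity and coverage estimators;
    Bray-Curtis beta diversity with distance-decay, Mantel, ANOSIM, and
    principal coordinates; spatial eigenfunctions (PCNM and directional
    asymmetric eigenvector maps on dendritic river networks); and RDA-based
    variation partitioning with collinearity filtering and forward selection.
    A synthetic-data module simulates neutral metacommunities with known
    immigration, dendritic river networks with coordinates, and
    niche-structured communities on environmental gradients, providing
    ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    igraph,
    jsonlite,
    MASS,
    stats,
    utils,
    vegan,
    withr,
    yaml
Suggests:
    car,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
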