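Package: carepathways
Title: Prenatal Care-Pathway Mining, Built-Environment Exposures, and
    Postpartum Depression Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying patterns of prenatal care and
    their relationship to the built environment and postpartum depression
    (PPD). Patients are compared by the longest-common-subsequence (LCS)
    distance between their ordered clinical event sequences and grouped by
    hierarchical clustering with silhouette-based model selection; common
    care pathways within each cluster are mined with a from-scratch SPADE
    (Sequential PAttern Discovery using Equivalence classes) frequent
    sequence miner; walkability and traffic-exposure indicators (bus stops,
    subway stations, bike-path length, green area, sidewalk area,
    intersections, light/heavy vehicle kilometres travelled, entropy-based
    land-use mix, retail floor-area ratio) are computed in Euclidean buffers
    around home locations from planar spatial layers, with census-tract
    pollution and social-determinants joins; and a recursive two-equation
    path model (multinomial logistic for cluster membership, binary logistic
    for PPD on cluster indicators) with chained-equation imputation and
    variance-inflation screening links the pieces. A seeded synthetic-data
    generator produces full study bundles (event sequences with planted
    cluster structure, spatial layers, tract attributes, outcomes) for
    validation and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    nnet,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
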