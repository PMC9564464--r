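Package: gravnet
Title: Spatial Association Networks of Regional Pollution via a Modified Gravity Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs directed spatial association networks among regions from a
    modified gravity model with IPAT-style masses (population, gross regional
    product, technology, pollutant concentration) and an asymmetric pollution-share
    weight, then analyses them with social network analysis: Krackhardt
    whole-network indices (density, connectedness, hierarchy, efficiency),
    degree/betweenness/closeness centrality, CONCOR blockmodeling with block-flow
    accounting and spillover-role classification, and QAP/MRQAP permutation
    inference for dyadic covariates. Includes a synthetic-data generator with
    planted block and dyadic structure for validation, packaged reference tables
    from a published province-level PM2.5 study, and a config-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
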