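Package: pignet
Title: Social Network Analysis of Co-Lying Behavior in Group-Housed Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds weighted social networks for pen-housed pigs from
    scan-sampled observations of lying behavior. Co-lying events are
    aggregated into pairwise frequency matrices, converted to half-weight
    association index (HWI) matrices, and summarized with weighted network
    measures: density, absent/weak/strong tie classification, per-animal
    strength, and eigenvector centrality. Resampling inference includes a
    node-bootstrap test of network density against a theoretical value,
    quadratic assignment procedure (QAP) matrix-permutation correlation,
    a two-group bootstrap for animal-level metrics, and a chi-square
    contingency test. A generative pen simulator with known ground-truth
    association structure supports validation and parameter recovery.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), igraph, vegan, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'scan-data.R'
    'scan-io.R'
    'association.R'
    'metrics.R'
    'inference.R'
    'simulate.R'
    'pipeline.R'
    'utils.R'
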