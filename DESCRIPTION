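Package: epicart
Title: Expression Cartography of Multi-Class Cohorts with Self-Organizing Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Portrays multi-class gene expression cohorts on self-organizing
    maps (SOM) of metagenes, detects class-specific overexpression spots,
    segments the map into quadrants and a central zone, tests gene-group
    enrichment in map regions with Fisher's exact test, scores differential
    expression with a shrinkage t-statistic, links spot modules through
    signed weighted topological overlap networks, and propagates
    expression-derived activity signals through cyclic metabolic pathways
    after linearization (Pathway Signal Flow). Includes a synthetic-cohort
    generator with planted co-expression modules so the whole pipeline can
    be exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
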