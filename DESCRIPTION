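Package: limbconn
Title: Structural Connectome Hierarchy Analysis of Limbic Subregions
Version: 0.1.0
Authors@R: person("Connectome", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for group analysis of weighted structural
    connectomes with hippocampal-subfield and amygdala-nucleus resolution:
    proportional sparsity thresholding, weighted nodal centrality features
    (strength, betweenness, clustering coefficient), area-under-the-curve
    summarization across a threshold range, covariate-adjusted permutation
    group inference with false discovery rate control, partial Spearman
    symptom associations, Table-1-style demographic statistics, and a seeded
    synthetic-cohort generator with planted effects providing ground truth
    for every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
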