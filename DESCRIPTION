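Package: conngraph
Title: Graph-Theoretic Analysis of Functional Connectomes Under a
    Two-Condition, Four-Session Repeated-Measures Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds density-thresholded binary brain networks from
    region-by-time signal matrices (Pearson correlation, Fisher r-to-z,
    proportional thresholding), computes the standard global measures
    (clustering, transitivity, modularity, characteristic path length,
    global and local efficiency, small-worldness against degree-preserving
    null models, assortativity) and nodal centralities (degree, betweenness,
    closeness, eigenvector, PageRank, K-coreness, subgraph, participation,
    diversity), and compares them across a 2 (condition) x 4 (time-of-day)
    within-subject design with repeated-measures ANOVA, Benjamini-Hochberg
    FDR across a density sweep, and a region-flagging rule. Includes a
    synthetic multi-subject cohort generator with planted modular structure
    and planted condition and time-of-day effects so that every stage of
    the pipeline can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
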