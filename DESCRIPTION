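Package: oligotraj
Title: Cross-Species Analysis of Oligodendrocyte Differentiation Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing oligodendrocyte differentiation programs
    across vertebrate species from single-cell RNA-seq count matrices.
    Provides ortholog harmonization to a reference symbol space, graph-based
    pseudotime ordering rooted at the progenitor (OPC) state, stage calling
    by marker module-score crossover, per-stage differential expression with
    effect-size and expression-fraction filters, a conservation taxonomy
    (core, high-shared, clade-exclusive), pseudotime-binned co-expression
    module discovery, and centroid-based cross-species stage mapping.
    Includes a five-species synthetic atlas generator with planted ground
    truth so that every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
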