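Package: treebic
Title: Biclustering of Tree-Shaped Time-Series Single-Cell Gene
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for gene-by-cell biclustering of time-series expression
    data measured along binary cell-lineage trees, as produced by 4D
    confocal imaging of Caenorhabditis elegans embryos. Expression
    trajectories are fitted per lineage subtree with piecewise polynomials
    constrained to be continuously differentiable at cell divisions, so
    that expression rate functions from embryos with non-pairwise time
    grids become comparable. Biclusters are then found by an elitist
    genetic algorithm maximizing a four-term objective: mean Pearson
    correlation of gene rate functions, mean over cell pairs of the
    minimum Kolmogorov-Smirnov p-value on expression increments, the
    expressed-entry count, and a penalty on overlap with previously
    accepted biclusters; the search stops against an empirical quantile
    of randomly initialized candidates. A synthetic lineage-data
    generator with planted biclusters, tidy accessors, ggplot2 plots and
    a small command-line interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
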