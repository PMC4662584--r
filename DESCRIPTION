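Package: beecomm
Title: Statistical Analysis of Honey Bee Gut Microbiome Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of a 16S amplicon count-table analysis
    pipeline for honey bee forager gut communities sampled from productive and
    unproductive colonies: rarefaction and pooled in-silico library resampling
    with percentile confidence intervals, Shannon diversity and Pielou
    evenness, per-taxon Kruskal-Wallis tests, stepwise Wilks'-lambda
    discriminant analysis with leave-one-out cross-validation, Spearman
    co-occurrence networks with Cytoscape-ready edge tables, and co-culture
    optical-density interaction scoring.  A Dirichlet-multinomial synthetic
    community generator reproduces the study design (14 colonies, seven
    apiaries, Orbaceae-dominated profiles) and exposes how taxon dominance and
    fixed sequencing depth alone induce negative co-occurrence correlations
    and mask rare taxa.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
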