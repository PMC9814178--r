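Package: mgsquant
Title: Quantitative Metagenomic Species Profiling and Case-Control Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative shotgun-metagenome analysis built around
    metagenomic species (MGS) pangenomes: attribution of multi-mapped reads by
    unique-count ratios, rarefaction and gene-length normalization of gene
    count tables, MGS quantification from marker genes with cell-count
    correction to absolute abundances, inference of functional module carriage
    from core and accessory genes, rank-based differential abundance with
    Benjamini-Hochberg control and Cliff's Delta effect sizes, covariate
    deconfounding of feature-status associations, Bray-Curtis beta diversity
    with PERMANOVA and principal coordinates analysis, and a synthetic-data
    generator with planted effects, a planted confounder and group-differing
    microbial load for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
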