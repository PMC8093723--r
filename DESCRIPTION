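Package: divpart
Title: Diversity Partitioning of Depth-Structured Reef Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coverage-standardized Hill-number diversity analysis for
    site-by-species count data along environmental (depth) gradients.
    Partitions taxonomic, functional, and phylogenetic gamma diversity into
    independent alpha and beta components (multiplicative framework),
    estimates sample coverage from singletons and doubletons, decomposes
    pairwise Sorensen dissimilarity into spatial turnover and nestedness,
    computes community-weighted means of categorical traits, and provides
    nonparametric shallow-versus-deep comparisons.  Includes a seeded
    metacommunity simulator (species sorting, mass effects, neutral) so that
    every stage of the pipeline can be tested against ground-truthed inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    vegan
Suggests:
    cluster,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
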