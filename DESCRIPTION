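Package: phylotracks
Title: Phylogeny-Anchored Protein Domain Architectures and Gene Neighborhoods
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Offline analysis of protein families in their phylogenomic
    context. Builds or accepts phylogenetic trees, resolves protein domain
    architectures from HMMER domain hits, extracts gene neighborhoods around
    query genes from genome annotations, clusters neighboring genes by shared
    domain content, calls operons by intergenic distance, and renders the tree
    with per-leaf feature tracks to deterministic JSON and SVG. Includes a
    seeded synthetic-data generator with known ground truth so every step is
    testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomeInfoDb,
    ggplot2,
    BiocGenerics,
    S4Vectors,
    igraph,
    jsonlite,
    purrr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
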