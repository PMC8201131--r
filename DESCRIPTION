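Package: structenrich
Title: Spatial Enrichment of Omics Changes on Macromolecular Complex
    Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps binary omics significance calls (transcriptome or
    proteome) onto macromolecular complex structures and tests whether
    changed proteins cluster in space. Builds a weighted protein-protein
    proximity network from residue centroids of a PDB/mmCIF structure,
    samples coherent structural regions by weighted random walks with a
    consensus rule and a greedy minimum edge set cover, and scores each
    region with a one-sided Fisher exact test plus Bonferroni correction.
    Includes the per-subunit abundance normalization, 60S-to-polysome
    log-ratio classification, and paralog response transforms that
    produce the binary inputs, together with seed-deterministic synthetic
    fixture generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
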