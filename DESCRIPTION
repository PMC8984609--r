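Package: phycofunc
Title: Genome-Centric Metabolic Profiling of Algal Phycosphere Microbiomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis toolkit for genome-centric (MAG-based)
    studies of seaweed-associated microbial communities. Scores and filters
    metagenome-assembled genomes by completeness and contamination, assigns
    metabolic pathways from KEGG Orthology annotations using a
    module-completeness rule gated on key enzymes, computes Faith's
    phylogenetic distance and phylogenetic gain on rooted genome trees,
    summarises trait-weighted relative abundances across samples, and draws
    analytic rarefaction curves. Ships a curated catalog of carbon-fixation,
    nitrogen, sulfur, phosphorus, cobalamin, auxin and ethylene-related
    modules, plus a synthetic-community generator with known ground truth
    for end-to-end testing.
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
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
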