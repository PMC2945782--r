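Package: adipomotif
Title: Regulator Discovery for Early Adipocyte Development by Promoter
    Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for discovering candidate
    transcriptional regulators of early adipocyte development from a
    multi-condition expression time course. Genes are assigned to
    treatment-specific expression clusters by intersecting
    direction-consistent Welch contrasts under per-contrast
    Benjamini-Hochberg control; strand-aware promoter windows are
    extracted around transcription start sites with aligned per-base
    conservation and deduplicated by an overlap rule; promoters are
    scanned with JASPAR/TRANSFAC position weight matrices under
    conservation masking; motif over-representation in a cluster is
    scored by a score-threshold-optimized hypergeometric test with
    Bonferroni correction and a fold-change floor; and human
    protein-interaction edges are mapped to mouse under a strict
    one-to-one ortholog rule to extract cluster-induced interaction
    modules. Seeded simulators generate every input with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    limma,
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    data.table,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
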