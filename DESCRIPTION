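Package: disevo
Title: Evolutionary Analysis of Intrinsic Disorder in Protein Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative studies of intrinsically disordered
    regions (IDRs) across proteomes and ortholog groups.  Calls IDRs from
    per-residue disorder score tracks, summarises IDP and IDR fractions per
    proteome, projects disorder masks through multiple sequence alignments
    to score disorder conservation between orthologs with the Jaccard
    index, clusters conservation profiles, tests protein-protein
    interaction enrichment of clusters against a Monte-Carlo null, detects
    compositionally biased regions with a maximal-scoring-segment method
    against homopolymers under BLOSUM62, and tabulates binary cross-species
    conservation patterns of biased regions.  Includes a fully seeded
    synthetic-data generator that plants known IDRs, conservation
    archetypes, biased segments and dense network modules so that every
    stage of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    grDevices,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
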