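Package: xregen
Title: Cross-Species Regeneration Time-Course Transcriptome Comparison
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing bulk time-course transcriptomes of
    regenerating animals across distantly related species. Transcripts are
    collapsed to gene units, annotated by best-scoring alignment hits against
    a curated reference protein database (human best-match and broader
    list-match annotation), and linked across species by shared annotation.
    Differential expression over replicate-free time courses is assessed with
    a negative-binomial exact test conditioned on the pairwise count total,
    with Benjamini-Hochberg correction, and differentially expressed genes
    are classified into transient (early up/down) and sustained (late up/down)
    temporal patterns on a rescaled common clock. Immune (macrophage,
    neutrophil) and epithelial-mesenchymal-transition gene signatures are
    matched against each species' annotation to produce presence/DE matrices.
    A seeded synthetic-data generator with planted ground truth supports
    validation of every stage, and a configuration-driven pipeline runs the
    full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
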