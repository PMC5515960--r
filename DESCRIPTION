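Package: natseek
Title: Genome-Wide Identification and Characterization of Natural Antisense Transcripts
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects natural antisense transcripts (NATs) from stranded gene
    models and assembled transcripts. Clusters genes and transcripts into
    same-strand transcript units, identifies cis-NAT candidates by
    opposite-strand overlap with a 10 percent length rule, identifies
    trans-NAT candidates by seeded reverse-complement matching with
    coverage and duplex bubble criteria, and applies a five-step
    non-coding filter cascade (length, open reading frame, protein
    similarity, coding potential, housekeeping and small RNA similarity).
    Downstream characterization includes sense-antisense pair configuration
    and relationship typing, RPKM stage-presence Venn partitioning,
    expression profile normalization and Pearson correlation with a
    directional t test, and hypergeometric functional-category enrichment
    with Benjamini-Hochberg false discovery rates. A seeded synthetic
    fixture generator with planted ground truth supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
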