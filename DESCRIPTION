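Package: miRscreen
Title: Functional microRNA Annotation and Seed-Match Target Scanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies functional microRNAs from offline evidence files by
    combining four integer criterion scores (literature support from a
    gene-to-PubMed map, cross-species conservation by perfect 5'-end 19-nt
    prefix identity, pooled reads-per-million expression from small-RNA-seq
    count tables, and a curated high-confidence flag) into a composite score
    with a fixed functional threshold, then selects the dominant and,
    where supported, a secondary mature arm per precursor.  Also provides a
    custom target-scanning workflow: validation of user miRNA (17-30 nt) and
    target (100-30000 nt) sequences, 7-mer seed-complementarity site finding
    on 3'-UTRs, a documented monotone surrogate score on the 50-100
    presentation scale, and ranked tab-delimited result tables.  A seeded
    synthetic-fixture generator emulates every input with planted ground
    truth so the whole pipeline is testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
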