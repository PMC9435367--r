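Package: raglscan
Title: Structural Annotation of RAG-Like and Transib Transposons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the structural side of RAG-like (RAGL) and Transib
    transposon biology: a bipartite terminal-inverted-repeat (TIR) motif
    model with log-odds scanning and threshold calibration, assembly of TIR
    hits into transposon calls with target-site-duplication (TSD)
    validation, ORF discovery and architecture classification, a
    domain-diagnostic classifier separating RAG1L from Transib subgroup I
    and II transposases, an insertion-polymorphism caller that interprets
    paired flanking sequences against a reference genome, group identity
    summaries with a neighbor-joining clan-partition check, and a seeded
    synthetic-genome generator that plants elements with known truth so
    every stage can be benchmarked end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
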