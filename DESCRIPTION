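Package: lnckit
Title: Integration and Characterization of Long Non-Coding RNA Annotations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a consolidated long non-coding RNA (lncRNA)
    annotation from multiple GFF3/GTF sources by cumulative stepwise
    intersection against a reference annotation, with full per-record fate
    accounting and source-membership (upset) reporting. Also computes
    tissue-specificity scores (Tau and the Preferential Expression Measure),
    TPM normalization, expression filtering with TMM-normalized log2-CPM,
    per-exon conservation-score aggregation over merged exons, and rule-based
    positional classification of lncRNA transcripts relative to reference
    mRNA transcripts (genic sense/antisense exonic/intronic
    overlapping/containing/nested; intergenic divergent/convergent/same-strand).
    Includes a seeded synthetic-fixture generator so every step is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
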