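Package: pgcmeth
Title: Windowed CpG Methylation Analysis of Germline Epigenetic Reprogramming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-genome bisulfite sequencing of mouse
    primordial germ cells and oocytes undergoing epigenetic reprogramming.
    Reads and filters CpG-level bisulfite call files in the standard coverage
    dialect, computes read-weighted methylation levels over fixed 10-kb genomic
    windows and arbitrary intervals, calls differentially methylated regions
    between matched control and knockout samples, aggregates methylation over
    repeat families and imprinting control regions, associates methylation
    changes with histone-mark enrichment, and classifies the cross-stage
    persistence of hypermethylated windows from embryonic germ cells to fully
    grown oocytes. Includes a deterministic synthetic-data generator producing a
    toy genome, annotations, chromatin tracks, and beta-binomial read counts
    with machine-readable truth tables for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
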