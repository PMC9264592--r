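Package: isocurate
Title: Splice Junction-Centric Curation of Long-Read Transcriptomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to curate transcript models from mapped long-read
    (Iso-seq) cDNA alignments. Implements per-read mismatch profiling
    around splice junctions and high-confidence junction calling;
    stratified binomial and sliding-window determination of transcription
    start and end sites with removal of genomically templated off-priming;
    transcript collapse, end-region filtering, annotation rescue and
    high-level merging into a reference transcript dataset (RTD);
    priority-based integration of short-read assemblies; positional motif
    validation of called sites against random controls; rule-based gene
    assignment including chimeric (read-through) gene naming and non-stop
    RNA detection; and a fully seeded synthetic-data generator with truth
    tables for end-to-end evaluation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    igraph,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
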