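test_that("FASTA reading normalises case and ids and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "acgtACGT", ">chr2", "NNNACGT"), f)
  g <- read_genome(f)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(as.character(g[["chr1"]]), "ACGTACGT")
  expect_equal(genome_lengths(g), c(chr1 = 8L, chr2 = 7L))
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_genome(g, f2)
  expect_equal(as.character(read_genome(f2)), as.character(g))
})

test_that("duplicate chromosome ids are rejected", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1", "ACGT", ">chr1", "ACGT"), f)
  expect_error(read_genome(f), "duplicate")
})

test_that("genome_fetch honours half-open bounds and degenerate intervals", {
  g <- make_genome(chr1 = "ACGTACGTAC")
  expect_equal(genome_fetch(g, "chr1", 0, 4), "ACGT")
  expect_equal(genome_fetch(g, "chr1", 5, 5), "")
  expect_equal(genome_fetch(g, "chr1", c(0, 8), c(2, 10)), c("AC", "AC"))
  expect_error(genome_fetch(g, "chr1", 0, 11), "out of bounds")
  expect_error(genome_fetch(g, "chr9", 0, 1), "absent")
})

test_that("reverse complement is an involution", {
  seqs <- c("ACGT", "GGGTTTAAA", "N", "")
  expect_equal(revcomp(revcomp(seqs)), seqs)
  expect_equal(revcomp("AACGT"), "ACGTT")
})

test_that("alignment TSV dialect round-trips a read set", {
  rs <- make_reads(
    list(id = "r1", blocks = blocks2(0, 100, 200, 300), cap = TRUE),
    list(id = "r2", strand = "-", blocks = blocks2(50, 150)),
    mismatches = data.frame(read_id = "r1", pos = 95L, kind = "sub", len = 1L))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alignments(rs, f)
  rs2 <- read_alignments(f)
  expect_equal(rs2$reads$read_id, sort(rs$reads$read_id))
  expect_equal(data.table::setkey(rs2$blocks, read_id, start),
               data.table::setkey(rs$blocks, read_id, start))
  expect_equal(rs2$mismatches$pos, 95L)
  expect_true(rs2$reads[read_id == "r1", cap])
  expect_false(rs2$reads[read_id == "r2", cap])
})

test_that("read_set enforces block invariants", {
  expect_error(make_reads(list(id = "r", blocks = blocks2(10, 10))), "empty")
  expect_error(make_reads(list(id = "r", blocks = blocks2(0, 100, 100, 200))),
               "abutting")
  expect_error(make_reads(list(id = "r", blocks = blocks2(0, 100, 50, 200))),
               "overlapping|abutting")
})

test_that("SAM records parse into blocks and MD-derived substitutions", {
  ref <- paste(rep("A", 400), collapse = "")
  g <- make_genome(chr1 = ref)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:400",
    # 10M 100N 10M, one substitution at read offset 5 (0-based), MD present
    paste("r1", 0, "chr1", 1, 60, "10M100N10M", "*", 0, 0,
          "AAAAACAAAAAAAAAAAAAA", "*", "MD:Z:5C14", sep = "\t"),
    # secondary record must be skipped
    paste("r2", 256, "chr1", 1, 60, "20M", "*", 0, 0,
          "AAAAAAAAAAAAAAAAAAAA", "*", "MD:Z:20", sep = "\t")), sam)
  rs <- read_alignments(sam, genome = g)
  expect_equal(nrow(rs$reads), 1L)
  expect_equal(attr(rs, "skipped"), 1L)
  expect_equal(rs$blocks$start, c(0L, 110L))
  expect_equal(rs$blocks$end, c(10L, 120L))
  expect_equal(rs$mismatches$pos, 5L)
  expect_equal(rs$mismatches$kind, "sub")
})

test_that("substitutions are recovered from the genome when MD is absent", {
  # 200-nt reference, read matches except one base
  set.seed(42)
  ref <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  g <- make_genome(chr1 = ref)
  rseq <- substr(ref, 11, 60)
  mismatch_at <- 25L  # read offset (1-based)
  bad <- setdiff(c("A", "C", "G", "T"), substr(rseq, mismatch_at, mismatch_at))[1L]
  substr(rseq, mismatch_at, mismatch_at) <- bad
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:200",
    paste("r1", 0, "chr1", 11, 60, "50M", "*", 0, 0, rseq, "*", sep = "\t")),
    sam)
  rs <- read_alignments(sam, genome = g)
  expect_equal(rs$mismatches$pos, 10L + mismatch_at - 1L)
  expect_equal(rs$mismatches$kind, "sub")
})

test_that("CIGAR indels become insertion and deletion events", {
  ref <- paste(rep("A", 100), collapse = "")
  g <- make_genome(chr1 = ref)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:chr1\tLN:100",
    paste("r1", 0, "chr1", 1, 60, "5M2D5M1I5M", "*", 0, 0,
          "AAAAAAAAAACAAAAA", "*", sep = "\t")), sam)
  rs <- read_alignments(sam, genome = g)
  mm <- rs$mismatches[order(pos)]
  expect_equal(mm$kind, c("del", "ins"))
  expect_equal(mm$pos, c(5L, 12L))
  expect_equal(mm$len, c(2L, 1L))
  # deletions stay inside one block (split only at N)
  expect_equal(nrow(rs$blocks), 1L)
})

test_that("BED12 round-trips transcript models exactly", {
  ts <- make_ts(
    list(id = "t1", blocks = blocks2(100, 200, 300, 400, 500, 600),
         cds = c(150, 550), support = 3L),
    list(id = "t2", strand = "-", blocks = blocks2(1000, 1200)))
  f <- withr::local_tempfile(fileext = ".bed")
  write_transcripts(ts, f, "bed")
  ts2 <- read_transcripts(f, "bed")
  expect_equal(ts2$transcripts$transcript_id, ts$transcripts$transcript_id)
  expect_equal(ts2$blocks, ts$blocks)
  expect_equal(ts2$transcripts$cds_start, ts$transcripts$cds_start)
  expect_equal(ts2$transcripts$cds_end, ts$transcripts$cds_end)
  expect_equal(ts2$transcripts$support, ts$transcripts$support)
})

test_that("GTF conversion uses 1-based inclusive exons and keeps attributes", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "test", "exon", 101, 200, ".", "+", ".",
                   'gene_id "gA"; transcript_id "t1";', sep = "\t"), f)
  ts <- read_transcripts(f, "gtf")
  expect_equal(ts$blocks$start, 100L)
  expect_equal(ts$blocks$end, 200L)
  expect_equal(ts$transcripts$gene_id, "gA")

  ts2 <- make_ts(list(id = "t1", gene = "A-B", blocks = blocks2(0, 50, 100, 150),
                      cds = c(10, 120), support = 5L, source = "isoseq"))
  f2 <- withr::local_tempfile(fileext = ".gtf")
  write_transcripts(ts2, f2, "gtf")
  txt <- readLines(f2)
  expect_true(any(grepl('gene_id "A-B"', txt)))
  back <- read_transcripts(f2, "gtf")
  expect_equal(back$blocks, ts2$blocks)
  expect_equal(back$transcripts$gene_id, "A-B")
  expect_equal(back$transcripts$support, 5L)
  expect_equal(back$transcripts$cds_start, 10L)
  expect_equal(back$transcripts$cds_end, 120L)
})

test_that("degenerate transcript IO cases behave", {
  empty <- transcript_set(
    data.frame(transcript_id = character(), chrom = character(),
               strand = character()),
    data.frame(transcript_id = character(), start = integer(),
               end = integer()))
  f <- withr::local_tempfile(fileext = ".bed")
  write_transcripts(empty, f, "bed")
  expect_equal(length(readLines(f)), 0L)
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines(paste("chr1", "x", "transcript", 1, 100, ".", "+", ".",
                   'gene_id "g"; transcript_id "t";', sep = "\t"), f2)
  expect_error(suppressWarnings(read_transcripts(f2, "gtf")), "no exon")
})

test_that("parameter files round-trip losslessly", {
  p <- pipeline_params(end_alpha = 0.01, sj_window = 25L)
  f <- withr::local_tempfile(fileext = ".json")
  write_params(p, f)
  p2 <- read_params(f)
  expect_equal(p2, p)
  expect_error(pipeline_params(sj_window = 0), "positive")
  expect_error(pipeline_params(rescue_overlap = 1.5), "in \\(0, 1\\]")
})
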