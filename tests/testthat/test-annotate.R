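ref_two_genes <- function() {
  make_ts(list(id = "A.1", gene = "A", blocks = blocks2(0, 1000)),
          list(id = "B.1", gene = "B", blocks = blocks2(2000, 3000)))
}

test_that("gene assignment uses the either-denominator 30% rule", {
  ref <- ref_two_genes()
  # 80% of the model inside gene A
  m1 <- make_ts(list(id = "t1", blocks = blocks2(100, 600)))
  a1 <- assign_genes(m1, ref, P)
  expect_equal(a1$gene_id, "A")
  expect_false(a1$chimeric)
  # exactly 30% of either party is NOT enough (strict greater-than)
  m2 <- make_ts(list(id = "t2", blocks = blocks2(700, 1700)))
  # overlap with A = 300 = 30% of both -> no match -> novel
  a2 <- assign_genes(m2, ref, P)
  expect_equal(a2$n_ref_genes, 0L)
  expect_match(a2$gene_id, "^G")
})

test_that("read-through models get concatenated chimeric ids in genome order", {
  ref <- ref_two_genes()
  m <- make_ts(list(id = "chim", blocks = blocks2(500, 2500)))
  a <- assign_genes(m, ref, P)
  expect_equal(a$gene_id, "A-B")
  expect_true(a$chimeric)
  # decomposes into existing reference ids
  expect_true(all(strsplit(a$gene_id, "-")[[1L]] %in% c("A", "B")))
})

test_that("novel gene ids are deterministic and shared within a locus", {
  ref <- ref_two_genes()
  m <- make_ts(list(id = "n1", blocks = blocks2(5000, 5500)),
               list(id = "n2", blocks = blocks2(5400, 5900)),
               list(id = "n3", blocks = blocks2(8000, 8200)))
  a <- assign_genes(m, ref, P)
  expect_equal(a[a$transcript_id == "n1", ]$gene_id,
               a[a$transcript_id == "n2", ]$gene_id)
  expect_false(a[a$transcript_id == "n3", ]$gene_id ==
                 a[a$transcript_id == "n1", ]$gene_id)
  a2 <- assign_genes(m, ref, P)
  expect_equal(a, a2)  # re-run reproduces identical ids
  # every transcript lands in exactly one gene bucket
  expect_equal(anyDuplicated(a$transcript_id), 0L)
  expect_false(anyNA(a$gene_id))
})

test_that("longest ORF handles stop, stopless and ATG-free transcripts", {
  # 30 coding codons then TAA, spliced across an intron
  orf_seq <- paste0("ATG", strrep("GCT", 29L), "TAA")
  pre <- "CCCCCC"; post <- "CCCCCCCC"
  tx <- paste0(pre, orf_seq, post)
  g <- make_genome(chr1 = paste0(substr(tx, 1, 50), strrep("G", 100),
                                 substr(tx, 51, nchar(tx))))
  ts <- make_ts(list(id = "t", blocks = blocks2(0, 50, 150, 150 + nchar(tx) - 50)))
  orf <- longest_orf(ts, g)
  expect_equal(orf$n_codons, 30L)
  expect_true(orf$has_terminal_stop)
  expect_equal(orf$orf_start, nchar(pre))
  expect_equal(orf$orf_end, nchar(pre) + 93L)
  # CDS genomic interval spans the intron
  expect_equal(orf$cds_start, 6L)
  expect_true(orf$cds_end > 150L)

  # no in-frame stop: CDS runs to the last full codon
  tx2 <- paste0("ATG", strrep("GCT", 20L), "GC")
  g2 <- make_genome(chr1 = tx2)
  ts2 <- make_ts(list(id = "t2", blocks = blocks2(0, nchar(tx2))))
  orf2 <- longest_orf(ts2, g2)
  expect_false(orf2$has_terminal_stop)
  expect_equal(orf2$n_codons, 21L)
  expect_equal(orf2$orf_end, 63L)

  # no ATG at all
  g3 <- make_genome(chr1 = strrep("C", 60))
  ts3 <- make_ts(list(id = "t3", blocks = blocks2(0, 60)))
  expect_true(is.na(longest_orf(ts3, g3)$orf_start))

  # minus strand: ORF read on the transcribed strand
  g4 <- make_genome(chr1 = revcomp(tx2))
  ts4 <- make_ts(list(id = "t4", strand = "-", blocks = blocks2(0, nchar(tx2))))
  expect_equal(longest_orf(ts4, g4)$n_codons, 21L)
})

test_that("non-stop detection applies the three rules in order", {
  # transcript whose ORF runs to the end (within 3 nt), gene TES 500 nt
  # beyond; a sibling transcript defines the gene's distal TES
  stopless <- paste0("ATG", strrep("GCT", 110L))
  glen <- 2000L
  g <- make_genome(chr1 = paste0(stopless, strrep("C", glen - nchar(stopless))))
  ts <- make_ts(
    list(id = "ns", blocks = blocks2(0, nchar(stopless))),
    list(id = "full", blocks = blocks2(0, nchar(stopless) + 500L)))
  orfs <- longest_orf(ts, g)
  asg <- data.table::data.table(transcript_id = c("ns", "full"),
                                gene_id = "G1", n_ref_genes = 1L,
                                chimeric = FALSE)
  calls <- detect_nonstop(ts, g, orfs, asg, P)
  expect_true(calls[transcript_id == "ns", verdict])
  expect_equal(calls[transcript_id == "ns", cds_end_gap], 0L)

  # rule 2: a stop codon ending 2 nt before the transcript end
  with_stop <- paste0("ATG", strrep("GCT", 110L), "TAACC")
  g2 <- make_genome(chr1 = paste0(with_stop, strrep("C", 1000L)))
  ts2 <- make_ts(list(id = "s", blocks = blocks2(0, nchar(with_stop))),
                 list(id = "full", blocks = blocks2(0, nchar(with_stop) + 500L)))
  orfs2 <- longest_orf(ts2, g2)
  asg2 <- data.table::data.table(transcript_id = c("s", "full"),
                                 gene_id = "G1", n_ref_genes = 1L,
                                 chimeric = FALSE)
  calls2 <- detect_nonstop(ts2, g2, orfs2, asg2, P)
  expect_false(calls2[transcript_id == "s", verdict])
  expect_true(calls2[transcript_id == "s", stop_in_tail])

  # rule 3: TES gap of exactly 80 nt (not > 100) fails
  ts3 <- make_ts(
    list(id = "ns", blocks = blocks2(0, nchar(stopless))),
    list(id = "full", blocks = blocks2(0, nchar(stopless) + 80L)))
  calls3 <- detect_nonstop(ts3, g, longest_orf(ts3, g), asg, P)
  expect_false(calls3[transcript_id == "ns", verdict])
  expect_equal(calls3[transcript_id == "ns", tes_gap], 80L)

  # rule 4: short-ORF genes are not protein coding
  short <- paste0("ATG", strrep("GCT", 10L))
  # stop-rich filler keeps every downstream frame closed
  g4 <- make_genome(chr1 = paste0(short, strrep("TAA", 500L)))
  ts4 <- make_ts(list(id = "ns", blocks = blocks2(0, nchar(short))),
                 list(id = "full", blocks = blocks2(0, nchar(short) + 500L)))
  asg4 <- data.table::data.table(transcript_id = c("ns", "full"),
                                 gene_id = "G1", n_ref_genes = 1L,
                                 chimeric = FALSE)
  calls4 <- detect_nonstop(ts4, g4, longest_orf(ts4, g4), asg4, P)
  expect_false(calls4[transcript_id == "ns", verdict])
  expect_false(calls4[transcript_id == "ns", coding_gene])
})

test_that("structure classification sums are internally consistent", {
  ts <- make_ts(
    list(id = "a1", blocks = blocks2(0, 100)),
    list(id = "a2", blocks = blocks2(0, 50, 80, 120, 150, 200)),
    list(id = "b1", blocks = blocks2(1000, 1100)),
    list(id = "c1", strand = "-", blocks = blocks2(2000, 2100, 2200, 2300)))
  asg <- data.table::data.table(
    transcript_id = c("a1", "a2", "b1", "c1"),
    gene_id = c("gA", "gA", "gB", "gC"),
    n_ref_genes = 1L, chimeric = FALSE)
  cls <- classify_structure(ts, asg, orfs = NULL, params = P)
  expect_equal(cls$totals$genes, 3L)
  expect_equal(cls$totals$transcripts, 4L)
  # a gene with any spliced transcript is multi-exonic
  expect_false(cls$genes[gene_id == "gA", mono_exonic])
  expect_true(cls$genes[gene_id == "gB", mono_exonic])
  expect_equal(cls$totals$mono_exonic_genes +
                 cls$totals$multi_exonic_genes, cls$totals$genes)
  expect_equal(cls$totals$single_isoform_genes, 2L)
})
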