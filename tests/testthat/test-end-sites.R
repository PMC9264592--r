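mono <- function(id, s, e, strand = "+", cap = TRUE, chrom = "chr1") {
  list(id = id, chrom = chrom, strand = strand, cap = cap,
       blocks = blocks2(s, e))
}

test_that("locus building is single-linkage on same-strand exonic overlap", {
  rs <- make_reads(mono("a", 0, 100), mono("b", 90, 200),
                   mono("c", 300, 400), mono("d", 395, 500, strand = "-"))
  loci <- build_loci(rs)
  l <- function(id) loci[read_id == id, locus_id]
  expect_equal(l("a"), l("b"))
  expect_false(l("b") == l("c"))
  expect_false(l("c") == l("d"))  # opposite strands never cluster
  # chain a-b, b-c overlapping, a and c disjoint -> one locus
  rs2 <- make_reads(mono("a", 0, 100), mono("b", 90, 210), mono("c", 200, 300))
  loci2 <- build_loci(rs2)
  expect_equal(length(unique(loci2$locus_id)), 1L)
  # abutting blocks (zero overlap) stay separate
  rs3 <- make_reads(mono("a", 0, 100), mono("b", 100, 200))
  expect_equal(length(unique(build_loci(rs3)$locus_id)), 2L)
})

test_that("annotation mode assigns reads to the maximal-overlap gene", {
  ann <- make_ts(list(id = "tA", gene = "gA", blocks = blocks2(0, 150)),
                 list(id = "tB", gene = "gB", blocks = blocks2(140, 400)))
  rs <- make_reads(mono("a", 100, 200), mono("b", 600, 700))
  loci <- build_loci(rs, annotation = ann)
  expect_equal(loci[read_id == "a", locus_id], "gB")  # 60 nt vs 50 nt
  expect_true(startsWith(loci[read_id == "b", locus_id], "L"))
})

test_that("end tallies follow strand convention and the cap filter", {
  rs <- make_reads(mono("a", 100, 200), mono("b", 100, 250),
                   mono("c", 120, 250))
  loci <- build_loci(rs)
  t5 <- tally_ends(loci, rs, "start5")
  expect_equal(t5[order(pos), pos], c(100L, 120L))
  expect_equal(t5[pos == 100L, k], 2L)
  # minus-strand spliced read: transcription-order start is the right end
  rsm <- make_reads(list(id = "m", strand = "-", cap = TRUE,
                         blocks = blocks2(0, 100, 200, 300)))
  t5m <- tally_ends(build_loci(rsm), rsm, "start5")
  expect_equal(t5m$pos, 299L)
  t3m <- tally_ends(build_loci(rsm), rsm, "end3")
  expect_equal(t3m$pos, 0L)
  # no cap-captured reads -> empty 5' tally
  rs_nc <- make_reads(mono("a", 0, 100, cap = FALSE))
  expect_equal(nrow(tally_ends(build_loci(rs_nc), rs_nc, "start5")), 0L)
  expect_equal(nrow(tally_ends(build_loci(rs_nc), rs_nc, "end3")), 1L)
})

test_that("off-priming flags A-rich downstream windows at the threshold", {
  base <- strrep("C", 200)
  mkg <- function(downstream10) {
    # read ends at position 99 (+): downstream window is [100, 110)
    make_genome(chr1 = paste0(strrep("C", 100), downstream10, strrep("C", 90)))
  }
  rs <- make_reads(mono("a", 0, 100))
  loci <- build_loci(rs)
  t3 <- tally_ends(loci, rs, "end3")
  flagged_with <- function(seq10) {
    g <- mkg(seq10)
    out <- flag_off_priming(t3, g, P)
    nrow(attr(out, "removed")) == 1L
  }
  expect_true(flagged_with("AAAAAAAAAA"))
  expect_false(flagged_with("ACGTACGTAC"))   # 2 A
  expect_true(flagged_with("AAAAAATTTT"))    # exactly 6 A: boundary
  expect_false(flagged_with("AAAAATTTTT"))   # 5 A
  # conservation: removed + retained reads == input reads
  g <- mkg("AAAAAAAAAA")
  out <- flag_off_priming(t3, g, P)
  expect_equal(attr(out, "removed_reads") + sum(out$k), sum(t3$k))
  # minus strand reads the transcribed strand (genomic T upstream)
  rsm <- make_reads(mono("m", 100, 200, strand = "-"))
  t3mi <- tally_ends(build_loci(rsm), rsm, "end3")
  gm <- make_genome(chr1 = paste0(strrep("C", 90), strrep("T", 10),
                                  strrep("C", 100)))
  outm <- flag_off_priming(t3mi, gm, P)
  expect_equal(nrow(attr(outm, "removed")), 1L)
})

test_that("binomial point mass matches the exact oracle over the grid", {
  # all m <= 25, k <= m, n <= 10 against an independent log-factorial oracle
  worst <- 0
  for (n in 1:10) for (m in 1:25) for (k in 0:m) {
    r <- stats::dbinom(k, m, 1 / n)
    o <- oracle_binom_pmf(k, m, 1 / n)
    if (o > 0) worst <- max(worst, abs(r - o) / o)
  }
  expect_lt(worst, 1e-12)
})

test_that("binomial calls require enrichment above the mean and Pr < alpha", {
  tally <- function(ks, strand = "+") {
    data.table::data.table(locus_id = "L1", side = "end3", chrom = "chr1",
                           strand = strand,
                           pos = seq(100L, by = 10L, length.out = length(ks)),
                           k = as.integer(ks))
  }
  # uniform 1-read positions: k > m/n fails everywhere
  expect_equal(nrow(binomial_calls(tally(rep(1L, 10L)), P)), 0L)
  # n=4, counts {12,1,1,1}: the k=12 position is significant with the
  # frozen oracle probability
  calls <- binomial_calls(tally(c(12L, 1L, 1L, 1L)), P)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$k, 12L)
  pr_expected <- oracle_binom_pmf(12L, 15L, 0.25)
  expect_lt(abs(calls$pr - pr_expected) / pr_expected, 1e-12)
  expect_lt(calls$pr, 0.05)
  # single location can never be significant (Pr(m,m,1) = 1)
  expect_equal(nrow(binomial_calls(tally(5L), P)), 0L)
  expect_equal(nrow(binomial_calls(tally(1L), P)), 0L)
})

test_that("significance is monotone in k above the mean", {
  for (m in c(10L, 20L)) for (n in c(3L, 5L)) {
    t <- data.table::data.table(locus_id = "L", side = "end3", chrom = "c",
                                strand = "+", pos = 1:n, k = 1L)
    # sweep the first position's k upward, keeping m fixed via the rest
    sig <- logical(m)
    for (k1 in 1:(m - n + 1L)) {
      kk <- c(k1, rep(1L, n - 1L))
      extra <- m - sum(kk)
      if (extra < 0) next
      kk[n] <- kk[n] + extra
      tt <- data.table::copy(t)[, k := as.integer(kk)]
      calls <- binomial_calls(tt, P)
      sig[k1] <- 1L %in% which(tt$pos %in% calls$pos)
    }
    first <- which(sig)[1L]
    if (!is.na(first)) expect_true(all(sig[first:(m - n + 1L)]))
  }
})

test_that("sliding-window support calls match brute-force enumeration", {
  wtally <- function(positions, strand = "+") {
    dt <- data.table::data.table(locus_id = "L1", side = "start5",
                                 chrom = "chr1", strand = strand,
                                 pos = as.integer(positions))
    dt[, list(k = .N), by = c("locus_id", "side", "chrom", "strand", "pos")]
  }
  # reads at 100 and 104: one collapsed call at the 5'-most position
  c1 <- window_support_calls(wtally(c(100, 104)), P)
  expect_equal(nrow(c1), 1L)
  expect_equal(c1$pos, 100L)
  expect_equal(c1$window_support, 2L)
  # distance 6 exceeds the half-window
  expect_equal(nrow(window_support_calls(wtally(c(100, 106)), P)), 0L)
  # three identical ends
  c3 <- window_support_calls(wtally(c(100, 100, 100)), P)
  expect_equal(c3$pos, 100L)
  expect_equal(c3$window_support, 3L)
  # minus strand: the 5'-most tie-break is the larger coordinate
  c4 <- window_support_calls(wtally(c(100, 104), strand = "-"), P)
  expect_equal(c4$pos, 104L)
  # loci with significant calls are excluded
  expect_equal(nrow(window_support_calls(wtally(c(100, 104)), P,
                                         exclude_loci = "L1")), 0L)
})

test_that("stratification is emergent: binomial first, window otherwise", {
  t <- data.table::data.table(
    locus_id = c(rep("big", 4L), rep("small", 2L)),
    side = "end3", chrom = "chr1", strand = "+",
    pos = c(100L, 110L, 120L, 130L, 500L, 503L),
    k = c(12L, 1L, 1L, 1L, 1L, 1L))
  calls <- call_ends(t, P)
  expect_equal(calls[locus_id == "big", status], "significant")
  expect_equal(calls[locus_id == "small", status], "supported")
})

test_that("end regions are inclusive 50-nt windows clipped to the chromosome", {
  g <- make_genome(chr1 = strrep("A", 2000))
  calls <- data.table::data.table(locus_id = c("a", "b", "c"), side = "end3",
                                  chrom = "chr1", strand = "+",
                                  pos = c(1000L, 20L, 1030L))
  r <- make_regions(calls, g, P)
  expect_equal(r$region_start, c(950L, 0L, 980L))
  expect_equal(r$region_end, c(1051L, 71L, 1081L))
  expect_equal(nrow(r), 3L)  # overlapping regions kept, never merged
})

test_that("summary arithmetic reproduces printed-precision means", {
  expect_equal(mean_calls_per_locus(61014, 17098), 3.57)
  expect_equal(mean_calls_per_locus(550022, 17098), 32.17)
  expect_equal(mean_calls_per_locus(84043, 16728), 5.02)
  expect_equal(mean_calls_per_locus(669642, 16728), 40.03)
  expect_equal(mean_calls_per_locus(0, 0), 0)
  expect_equal(retained_after_removal(723903, 11703), 712200)
  expect_equal(retention_percent(124328 - 711, 124328), 99.43)
  expect_equal(reduction_percent(13619, 4477), 67)
})

test_that("summarize_end_detection aggregates per side", {
  t <- data.table::data.table(
    locus_id = c("L1", "L1", "L1", "L2"), side = "end3", chrom = "chr1",
    strand = "+", pos = c(100L, 110L, 120L, 500L), k = c(10L, 1L, 1L, 1L))
  calls <- call_ends(t, P)
  s <- summarize_end_detection(calls, t, removed_reads = 2L)
  expect_equal(s$total_locations, 4L)
  expect_equal(s$significant_calls, 1L)
  expect_equal(s$loci_with_calls, 1L)
  expect_equal(s$locations_in_significant_loci, 3L)
  expect_equal(s$mean_locations_per_locus, 3)
  expect_equal(s$removed_offpriming_reads, 2L)
})
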