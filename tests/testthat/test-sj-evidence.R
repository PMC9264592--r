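# a 300-nt toy chromosome with a GT-AG intron at [100, 200)
sj_genome <- function(strand = "+") {
  if (strand == "+") {
    make_genome(chr1 = toy_chrom(300L, at = c(100L, 101L, 198L, 199L),
                                 base = c("G", "T", "A", "G")))
  } else {
    # transcribed-strand GT-AG: genome shows CT at the left intron edge
    # and AC at the right edge
    make_genome(chr1 = toy_chrom(300L, at = c(100L, 101L, 198L, 199L),
                                 base = c("C", "T", "A", "C")))
  }
}

two_block <- function(id, strand = "+", mism = NULL, cap = FALSE) {
  make_reads(list(id = id, strand = strand,
                  blocks = blocks2(0, 100, 200, 300), cap = cap),
             mismatches = mism)
}

test_that("junction extraction records motif and offsets in transcription order", {
  g <- sj_genome("+")
  ev <- extract_junction_evidence(two_block("r1"), g, P)
  expect_equal(nrow(ev$junctions), 1L)
  expect_equal(ev$junctions$intron_start, 100L)
  expect_equal(ev$junctions$intron_end, 200L)
  expect_equal(ev$junctions$motif, "GTAG")
  expect_equal(nrow(ev$offsets), 0L)

  # substitution 5 nt into the upstream exon
  mm <- data.frame(read_id = "r1", pos = 95L, kind = "sub", len = 1L)
  ev2 <- extract_junction_evidence(two_block("r1", mism = mm), g, P)
  expect_equal(ev2$offsets$side, "up")
  expect_equal(ev2$offsets$offset, 5L)
})

test_that("minus-strand offsets flip sides", {
  # hand enumeration: on '-' the [200,300) block is the transcription-order
  # upstream exon; a substitution at 205 is 6 nt from the junction
  g <- sj_genome("-")
  mm <- data.frame(read_id = "r1", pos = 205L, kind = "sub", len = 1L)
  ev <- extract_junction_evidence(two_block("r1", strand = "-", mism = mm), g, P)
  expect_equal(ev$junctions$motif, "GTAG")
  expect_equal(ev$offsets$side, "up")
  expect_equal(ev$offsets$offset, 6L)
})

test_that("deletions contribute their footprint and insertions the nearer base", {
  g <- sj_genome("+")
  mm <- data.frame(read_id = "r1",
                   pos = c(96L, 200L), kind = c("del", "ins"), len = c(3L, 1L))
  ev <- extract_junction_evidence(two_block("r1", mism = mm), g, P)
  off <- ev$offsets[order(side, offset)]
  # deletion covers 96,97,98 -> upstream offsets 2,3,4
  expect_equal(off[side == "up", offset], c(2L, 3L, 4L))
  # insertion before 200 sits at the junction; nearer exonic base is 200
  # on the downstream side -> offset 1
  expect_equal(off[side == "down", offset], 1L)
})

test_that("offsets beyond the window or the exon edge are not recorded", {
  g <- sj_genome("+")
  mm <- data.frame(read_id = "r1", pos = c(70L, 69L, 230L, 10L),
                   kind = "sub", len = 1L)
  ev <- extract_junction_evidence(two_block("r1", mism = mm), g, P)
  # 70 -> up offset 30 (kept); 69 -> 31, 230 -> down 31 (both out); 10 far
  expect_equal(ev$offsets$offset, 30L)
  # short exon truncates the window at the exon edge
  rs <- make_reads(list(id = "r2", blocks = blocks2(85, 100, 200, 300)),
                   mismatches = data.frame(read_id = "r2", pos = 80L,
                                           kind = "sub", len = 1L))
  ev2 <- extract_junction_evidence(rs, g, P)
  expect_equal(nrow(ev2$offsets), 0L)  # outside the aligned exon
})

test_that("best observation minimises mismatches with near-window tie-break", {
  g <- sj_genome("+")
  mk <- function(id, positions) {
    list(id = id, blocks = blocks2(0, 100, 200, 300))
  }
  mm <- data.table::rbindlist(list(
    data.frame(read_id = "a", pos = c(95L, 96L, 97L, 98L), kind = "sub", len = 1L),
    data.frame(read_id = "c", pos = c(90L, 205L), kind = "sub", len = 1L)))
  rs <- make_reads(mk("a"), mk("b"), mk("c"), mismatches = mm)
  ev <- extract_junction_evidence(rs, g, P)
  expect_equal(ev$junctions$best_read, "b")
  expect_equal(ev$junctions$best_total60, 0L)
  expect_equal(ev$junctions$support, 3L)

  # tie on total: offset-25 read beats offset-3 read (near-window rule)
  mm2 <- data.table::rbindlist(list(
    data.frame(read_id = "a", pos = 97L, kind = "sub", len = 1L),   # offset 3
    data.frame(read_id = "b", pos = 75L, kind = "sub", len = 1L)))  # offset 25
  ev2 <- extract_junction_evidence(make_reads(mk("a"), mk("b"),
                                              mismatches = mm2), g, P)
  expect_equal(ev2$junctions$best_read, "b")
})

test_that("mismatch profile counts best observations and conserves totals", {
  g <- sj_genome("+")
  mk <- function(id, s) list(id = id, blocks = blocks2(0 + s, 100, 200, 300 + s))
  # 4 distinct junction-supporting single reads via distinct block starts is
  # overkill; use 4 reads on 2 junctions instead
  rs <- make_reads(
    list(id = "a", blocks = blocks2(0, 100, 200, 300)),
    list(id = "b", chrom = "chr2", blocks = blocks2(0, 100, 200, 300)),
    mismatches = data.frame(read_id = c("a", "a"), pos = c(98L, 97L),
                            kind = "sub", len = 1L))
  g2 <- make_genome(chr1 = as.character(g[[1L]]), chr2 = as.character(g[[1L]]))
  ev <- extract_junction_evidence(rs, g2, P)
  prof <- mismatch_profile(ev, "up")
  expect_equal(prof[position == 2L, count], 1L)
  expect_equal(prof[position == 3L, count], 1L)
  expect_equal(prof[position == 2L, percent], 50)
  # conservation: column sums equal the best observations' offset counts
  expect_equal(sum(prof$count), 2L)
  expect_error(mismatch_profile(ev, "up", junctions = character()), "empty")
})

test_that("retention curve matches brute force and is monotone", {
  g <- make_genome(chr1 = toy_chrom(300L, at = c(100L, 101L, 198L, 199L),
                                    base = c("G", "T", "A", "G")),
                   chr2 = toy_chrom(300L, at = c(100L, 101L, 198L, 199L),
                                    base = c("G", "T", "A", "G")),
                   chr3 = toy_chrom(300L, at = c(100L, 101L, 198L, 199L),
                                    base = c("G", "T", "A", "G")))
  # three junctions with nearest best-observation offsets 1, 5, none
  rs <- make_reads(
    list(id = "a", chrom = "chr1", blocks = blocks2(0, 100, 200, 300)),
    list(id = "b", chrom = "chr2", blocks = blocks2(0, 100, 200, 300)),
    list(id = "c", chrom = "chr3", blocks = blocks2(0, 100, 200, 300)),
    mismatches = data.frame(read_id = c("a", "b"), pos = c(99L, 95L),
                            kind = "sub", len = 1L))
  ev <- extract_junction_evidence(rs, g, P)
  rc <- retention_curve(ev)
  brute <- function(n) {
    nearest <- c(1L, 5L, NA_integer_)
    100 * sum(is.na(nearest) | nearest > n) / 3
  }
  expect_equal(rc$percent_remaining, vapply(1:30, brute, numeric(1L)))
  expect_equal(round(rc$percent_remaining[1L], 2), 66.67)
  expect_equal(round(rc$percent_remaining[5L], 2), 33.33)
  expect_true(all(diff(rc$percent_remaining) <= 0))
  # all clean -> 100% everywhere
  ev2 <- extract_junction_evidence(make_reads(
    list(id = "a", blocks = blocks2(0, 100, 200, 300))), g, P)
  expect_true(all(retention_curve(ev2)$percent_remaining == 100))
})

test_that("high-confidence calling partitions junctions with ordered reasons", {
  gplus <- sj_genome("+")
  # GT-AG junction with one dirty and one clean read -> HC
  mm <- data.frame(read_id = "a", pos = c(95L, 99L), kind = "sub", len = 1L)
  rs <- make_reads(list(id = "a", blocks = blocks2(0, 100, 200, 300)),
                   list(id = "b", blocks = blocks2(0, 100, 200, 300)),
                   mismatches = mm)
  hc <- call_high_confidence(extract_junction_evidence(rs, gplus, P))
  expect_true(hc$hc)

  # all observations dirty within 10 nt -> no_clean_read
  rs2 <- make_reads(list(id = "a", blocks = blocks2(0, 100, 200, 300)),
                    mismatches = data.frame(read_id = "a", pos = 95L,
                                            kind = "sub", len = 1L))
  hc2 <- call_high_confidence(extract_junction_evidence(rs2, gplus, P))
  expect_false(hc2$hc)
  expect_equal(hc2$reason, "no_clean_read")

  # deletion whose footprint touches the near window also disqualifies
  rs2b <- make_reads(list(id = "a", blocks = blocks2(0, 100, 200, 300)),
                     mismatches = data.frame(read_id = "a", pos = 85L,
                                             kind = "del", len = 6L))
  hc2b <- call_high_confidence(extract_junction_evidence(rs2b, gplus, P))
  expect_equal(hc2b$reason, "no_clean_read")

  # CT-AC motif (antisense-looking) with a perfectly clean read is
  # rejected as non-canonical first
  gminus_like <- make_genome(chr1 = toy_chrom(300L,
                                              at = c(100L, 101L, 198L, 199L),
                                              base = c("C", "T", "A", "C")))
  rs3 <- make_reads(list(id = "a", blocks = blocks2(0, 100, 200, 300)))
  hc3 <- call_high_confidence(extract_junction_evidence(rs3, gminus_like, P))
  expect_false(hc3$hc)
  expect_equal(hc3$reason, "non_canonical")
  expect_equal(hc3$motif, "CTAC")

  # partition property
  all_hc <- data.table::rbindlist(list(hc, hc2, hc3))
  expect_true(all(xor(all_hc$hc, !is.na(all_hc$reason))))
})

test_that("PWM training on identical sites scores the consensus 100", {
  # one junction repeated: train and score on itself
  g <- sj_genome("+")
  rs <- make_reads(list(id = "a", blocks = blocks2(0, 100, 200, 300)))
  ev <- extract_junction_evidence(rs, g, P)
  pwm <- train_pwm(ev$junctions, g, P)
  sc <- score_junctions(ev$junctions, pwm, g, P)
  expect_equal(sc$score5, 100)
  expect_equal(sc$score3, 100)
  expect_error(train_pwm(ev$junctions[0L], g, P), "empty")
})

test_that("uniform random training gives ~50 scaled scores on random sites", {
  set.seed(99)
  n <- 2000L
  glen <- 400L
  # build n junctions on one long random chromosome list
  seqs <- paste(sample(c("A", "C", "G", "T"), 120000, replace = TRUE),
                collapse = "")
  g <- make_genome(chr1 = seqs)
  jx <- data.table::data.table(
    chrom = "chr1", strand = "+",
    intron_start = seq(50L, by = 55L, length.out = n))
  jx[, intron_end := intron_start + 30L]
  jx[, key := paste0("j", .I)]
  pwm <- train_pwm(jx, g, P)
  sc <- score_junctions(jx, pwm, g, P)
  expect_gt(mean(sc$score5), 40); expect_lt(mean(sc$score5), 60)
  expect_gt(mean(sc$score3), 40); expect_lt(mean(sc$score3), 60)
})

test_that("a toy PWM matches direct arithmetic on enumerated inputs", {
  # hand-build counts via a controlled 2-junction training set and check
  # the scaled score formula 100*(raw-min)/(max-min) against direct
  # computation from the stored matrices
  g <- sj_genome("+")
  rs <- make_reads(list(id = "a", blocks = blocks2(0, 100, 200, 300)))
  ev <- extract_junction_evidence(rs, g, P)
  pwm <- train_pwm(ev$junctions, g, P)
  w_donor <- genome_fetch(g, "chr1", 100L - 3L, 100L + 10L)
  chars <- strsplit(w_donor, "")[[1L]]
  raw <- sum(vapply(seq_along(chars),
                    function(p) pwm$donor[chars[p], p], numeric(1L)))
  manual <- 100 * (raw - pwm$donor_min) / (pwm$donor_max - pwm$donor_min)
  sc <- score_junctions(ev$junctions, pwm, g, P)
  expect_equal(sc$score5, manual, tolerance = 1e-12)
})
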