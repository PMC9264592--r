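#' Assign gene identities to transcript models
#'
#' A reference gene matches a model when their same-strand exonic overlap
#' exceeds `params$gene_overlap` of EITHER the model's or the reference
#' transcript's exonic length. Models matching two or more genes get a
#' hyphen-concatenated chimeric id in genome coordinate order; models
#' matching none are clustered into novel loci and numbered "G<serial>" in
#' genome order, so re-runs on identical input reproduce identical ids.
#'
#' @param ts a [transcript_set()].
#' @param reference a [transcript_set()] whose `gene_id` column defines the
#'   reference genes.
#' @param params a [pipeline_params()].
#' @return data.table mapping transcript_id to gene_id, with `n_ref_genes`
#'   (0 for novel) and `chimeric` flag.
#' @export
assign_genes <- function(ts, reference, params = pipeline_params()) {
  tr <- ts$transcripts
  ref <- data.table::copy(reference$transcripts)
  ref[is.na(gene_id), gene_id := transcript_id]
  refx <- transcript_set(ref, reference$blocks, validate = FALSE)
  matches <- NULL
  if (nrow(ref)) {
    ov <- pairwise_exonic_overlap(ts, refx)
    alen <- ts_exonic_length(ts)
    blen <- ts_exonic_length(refx)
    ov <- merge(ov, alen, by.x = "a_id", by.y = "transcript_id")
    ov <- merge(ov, blen, by.x = "b_id", by.y = "transcript_id",
                suffixes = c("", ".ref"))
    thr <- params$gene_overlap
    ov <- ov[olap > thr * exonic_len | olap > thr * exonic_len.ref]
    ov[, gene_id := ref$gene_id[match(b_id, ref$transcript_id)]]
    gstart <- ref[, list(gstart = min(start)), by = gene_id]
    matches <- unique(ov[, c("a_id", "gene_id")])
    matches <- merge(matches, gstart, by = "gene_id")
    data.table::setorder(matches, a_id, gstart, gene_id)
    matches <- matches[, list(gene_id = paste(gene_id, collapse = "-"),
                              n_ref_genes = .N), by = a_id]
  }
  out <- data.table::data.table(transcript_id = tr$transcript_id)
  if (!is.null(matches) && nrow(matches)) {
    out <- merge(out, matches, by.x = "transcript_id", by.y = "a_id",
                 all.x = TRUE)
  } else {
    out[, `:=`(gene_id = NA_character_, n_ref_genes = NA_integer_)]
  }
  novel_ids <- out[is.na(gene_id), transcript_id]
  if (length(novel_ids)) {
    nov <- ts_subset(ts, novel_ids)
    loc <- model_loci(nov)
    # serials in genome order of each locus's leftmost model
    pos <- merge(loc, nov$transcripts[, c("transcript_id", "chrom", "start")],
                 by = "transcript_id")
    lpos <- pos[, list(chrom = min(chrom), start = min(start)), by = locus]
    data.table::setorder(lpos, chrom, start)
    lpos[, novel_gene := sprintf("G%04d", seq_len(.N))]
    loc <- merge(loc, lpos[, c("locus", "novel_gene")], by = "locus")
    out[loc, `:=`(gene_id = i.novel_gene, n_ref_genes = 0L),
        on = "transcript_id"]
  }
  out[, chimeric := n_ref_genes >= 2L]
  data.table::setorder(out, transcript_id)
  out[]
}

# spliced transcript sequence in transcription order, plus the
# transcript-to-genome coordinate map
spliced_sequences <- function(ts, genome) {
  bl <- merge(ts$blocks, ts$transcripts[, c("transcript_id", "chrom", "strand")],
              by = "transcript_id")
  data.table::setkey(bl, transcript_id, start)
  seqs <- genome_fetch(genome, bl$chrom, bl$start, bl$end)
  sp <- split(seqs, bl$transcript_id)
  strands <- bl[, strand[1L], by = transcript_id]
  out <- data.table::data.table(
    transcript_id = names(sp),
    seq = vapply(sp, paste, character(1L), collapse = ""))
  out <- merge(out, strands, by = "transcript_id")
  data.table::setnames(out, "V1", "strand")
  out[strand == "-", seq := revcomp(seq)]
  out[, c("transcript_id", "seq"), with = FALSE]
}

# genomic coordinate of each transcript-space position (0-based)
tx_to_genome <- function(ts, transcript_id, tx_pos) {
  strand <- ts$transcripts$strand[match(transcript_id,
                                        ts$transcripts$transcript_id)]
  vapply(seq_along(transcript_id), function(i) {
    b <- ts$blocks[transcript_id[i], on = "transcript_id"]
    w <- b$end - b$start
    if (strand[i] == "-") { b <- b[rev(seq_len(nrow(b)))]; w <- rev(w) }
    cum <- cumsum(c(0L, w))
    j <- findInterval(tx_pos[i], cum, rightmost.closed = FALSE)
    off <- tx_pos[i] - cum[j]
    if (strand[i] == "+") b$start[j] + off else b$end[j] - 1L - off
  }, numeric(1L))
}

#' Longest open reading frame of each transcript
#'
#' Finds the longest ATG-initiated ORF on the transcribed strand of each
#' model's spliced sequence. When no in-frame stop occurs before the
#' transcript end the CDS extends to the last full codon and
#' `has_terminal_stop` is FALSE. The genomic `cds_start`/`cds_end`
#' interval spans from the first to one past the last CDS base.
#'
#' @param ts a [transcript_set()].
#' @param genome a `DNAStringSet`.
#' @return data.table with transcript_id, tx_len, orf_start, orf_end
#'   (0-based transcript coordinates, end exclusive, stop codon included
#'   when present), n_codons (excluding the stop), has_terminal_stop, and
#'   genomic cds_start/cds_end; transcripts with no ATG have NA ORF fields.
#' @export
longest_orf <- function(ts, genome) {
  sq <- spliced_sequences(ts, genome)
  res <- lapply(seq_len(nrow(sq)), function(i) {
    s <- sq$seq[i]
    L <- nchar(s)
    atg <- as.integer(gregexpr("ATG", s, fixed = TRUE)[[1L]])
    atg <- atg[atg > 0L]
    if (!length(atg)) {
      return(data.table::data.table(transcript_id = sq$transcript_id[i],
                                    tx_len = L, orf_start = NA_integer_,
                                    orf_end = NA_integer_,
                                    n_codons = NA_integer_,
                                    has_terminal_stop = NA))
    }
    stops <- sort(unique(unlist(lapply(c("TAA", "TAG", "TGA"), function(cd)
      as.integer(gregexpr(cd, s, fixed = TRUE)[[1L]])))))
    stops <- stops[stops > 0L]
    best <- list(start = NA_integer_, end = NA_integer_, codons = -1L,
                 stop = NA)
    for (f in 0:2) {
      fa <- atg[(atg - 1L) %% 3L == f]
      if (!length(fa)) next
      fs <- stops[(stops - 1L) %% 3L == f]
      for (a in fa) {
        ns <- fs[fs >= a + 3L]
        if (length(ns)) {
          cod <- (ns[1L] - a) %/% 3L      # coding codons, stop excluded
          endp <- ns[1L] + 3L - 1L        # ORF end includes the stop codon
          term <- TRUE
        } else {
          cod <- (L - a + 1L) %/% 3L      # runs to the last full codon
          endp <- a + cod * 3L - 1L
          term <- FALSE
        }
        if (cod > best$codons)
          best <- list(start = a - 1L, end = endp, codons = cod, stop = term)
      }
    }
    data.table::data.table(transcript_id = sq$transcript_id[i], tx_len = L,
                           orf_start = as.integer(best$start),
                           orf_end = as.integer(best$end),
                           n_codons = as.integer(best$codons),
                           has_terminal_stop = best$stop)
  })
  out <- data.table::rbindlist(res)
  ok <- which(!is.na(out$orf_start))
  out[, `:=`(cds_start = NA_integer_, cds_end = NA_integer_)]
  if (length(ok)) {
    g1 <- tx_to_genome(ts, out$transcript_id[ok], out$orf_start[ok])
    g2 <- tx_to_genome(ts, out$transcript_id[ok], out$orf_end[ok] - 1L)
    out$cds_start[ok] <- as.integer(pmin(g1, g2))
    out$cds_end[ok] <- as.integer(pmax(g1, g2) + 1L)
  }
  out[]
}

#' Detect non-stop RNAs
#'
#' Applies, in order: (1) the CDS must end within `nonstop_cds_slack` nt of
#' the transcript end (strict less-than, transcript coordinates); (2) no
#' in-frame stop codon may end within the last `nonstop_stop_window` nt of
#' the transcript; (3) the gene's most distal TES must lie more than
#' `nonstop_tes_gap` nt beyond the transcript end in transcription order;
#' (4) transcripts of non-protein-coding genes (no transcript with an ORF
#' of `orf_min_codons` or more) are removed. Models without a CDS are
#' skipped and counted in the `skipped_no_cds` attribute.
#'
#' @param ts a [transcript_set()].
#' @param genome a `DNAStringSet` (for the in-frame tail stop check).
#' @param orfs output of [longest_orf()] for `ts`.
#' @param assignment output of [assign_genes()] for `ts`.
#' @param params a [pipeline_params()].
#' @param gene_tes optional data.table gene_id/tes giving the reference TES
#'   per gene; defaults to the most distal transcript end within `ts`.
#' @return data.table with transcript_id, gene_id, cds_end_gap,
#'   stop_in_tail, tes_gap, coding_gene, verdict.
#' @export
detect_nonstop <- function(ts, genome, orfs, assignment,
                           params = pipeline_params(), gene_tes = NULL) {
  d <- merge(orfs, assignment[, c("transcript_id", "gene_id")],
             by = "transcript_id")
  skipped <- sum(is.na(d$orf_start))
  d <- d[!is.na(orf_start)]
  d[, cds_end_gap := tx_len - orf_end]
  # in-frame stop codon ending within the tail window
  sq <- spliced_sequences(ts, genome)
  d <- merge(d, sq, by = "transcript_id")
  d[, stop_in_tail := mapply(function(s, a, L) {
    tailw <- params$nonstop_stop_window
    starts <- seq.int(a + 1L, L - 2L, by = 3L)  # ORF-frame codon starts
    starts <- starts[starts + 2L > L - tailw]
    any(substring(s, starts, starts + 2L) %in% c("TAA", "TAG", "TGA"))
  }, seq, orf_start, tx_len)]
  ends <- ts_tx_ends(ts)
  d <- merge(d, ends[, c("transcript_id", "strand", "tx_end")],
             by = "transcript_id")
  if (is.null(gene_tes)) {
    ge <- merge(ends, assignment[, c("transcript_id", "gene_id")],
                by = "transcript_id")
    gene_tes <- ge[, list(tes = if (strand[1L] == "+") max(tx_end)
                          else min(tx_end)), by = gene_id]
  }
  d <- merge(d, gene_tes, by = "gene_id")
  d[, tes_gap := ifelse(strand == "+", tes - tx_end, tx_end - tes)]
  coding <- d[, list(coding_gene = any(n_codons >= params$orf_min_codons)),
              by = gene_id]
  d <- merge(d, coding, by = "gene_id")
  d[, verdict := cds_end_gap < params$nonstop_cds_slack &
      !stop_in_tail &
      tes_gap > params$nonstop_tes_gap &
      coding_gene]
  out <- d[, c("transcript_id", "gene_id", "cds_end_gap", "stop_in_tail",
               "tes_gap", "coding_gene", "verdict")]
  data.table::setattr(out, "skipped_no_cds", skipped)
  out[]
}

#' Gene and transcript structure classes
#'
#' Per-gene summary: mono- vs multi-exonic (a gene is mono-exonic iff all
#' its transcripts are single-block), transcript count and coding status
#' (>= 1 transcript with an ORF of `orf_min_codons` codons), plus totals.
#'
#' @param ts a [transcript_set()].
#' @param assignment output of [assign_genes()].
#' @param orfs output of [longest_orf()] (optional; without it coding
#'   status is NA).
#' @param params a [pipeline_params()].
#' @return list with `genes` (per-gene table) and `totals`.
#' @export
classify_structure <- function(ts, assignment, orfs = NULL,
                               params = pipeline_params()) {
  d <- merge(ts$transcripts[, c("transcript_id", "n_blocks")],
             assignment[, c("transcript_id", "gene_id")], by = "transcript_id")
  if (!is.null(orfs)) {
    d <- merge(d, orfs[, c("transcript_id", "n_codons")], by = "transcript_id",
               all.x = TRUE)
  } else d[, n_codons := NA_integer_]
  genes <- d[, list(n_transcripts = .N,
                    mono_exonic = all(n_blocks == 1L),
                    coding = if (all(is.na(n_codons))) NA else
                      any(n_codons >= params$orf_min_codons, na.rm = TRUE)),
             by = gene_id]
  totals <- list(
    genes = nrow(genes),
    transcripts = nrow(d),
    mono_exonic_genes = sum(genes$mono_exonic),
    multi_exonic_genes = sum(!genes$mono_exonic),
    single_isoform_genes = sum(genes$n_transcripts == 1L),
    coding_genes = sum(genes$coding, na.rm = TRUE))
  stopifnot(totals$mono_exonic_genes + totals$multi_exonic_genes ==
              totals$genes)
  list(genes = genes[], totals = totals)
}
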