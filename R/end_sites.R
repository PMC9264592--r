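#' Group reads into loci
#'
#' Default mode clusters same-strand reads whose exonic footprints overlap
#' by at least 1 nt, with single-linkage transitivity. In annotation mode,
#' reads are first assigned to the annotated gene with maximal exonic
#' overlap on the same strand; unassigned reads fall back to clustering.
#'
#' @param rs a [read_set()].
#' @param annotation optional [transcript_set()] of gene models.
#' @return data.table mapping `read_id` to `locus_id`, with locus span
#'   columns chrom, strand, start, end attached per row's locus.
#' @export
build_loci <- function(rs, annotation = NULL) {
  reads <- rs$reads
  assign <- NULL
  rest_ids <- reads$read_id
  if (!is.null(annotation)) {
    assign <- assign_reads_to_genes(rs, annotation)
    rest_ids <- setdiff(reads$read_id, assign$read_id)
  }
  clus <- if (length(rest_ids)) cluster_reads(rs, rest_ids) else NULL
  out <- data.table::rbindlist(list(assign, clus), use.names = TRUE)
  out <- merge(out, reads[, c("read_id", "chrom", "strand")], by = "read_id")
  span <- merge(out, rs$blocks, by = "read_id")[
    , list(start = min(start), end = max(end)), by = locus_id]
  out <- merge(out, span, by = "locus_id")
  data.table::setkey(out, locus_id)
  out[]
}

# single-linkage clustering of reads by exonic overlap (>= 1 nt, same strand)
cluster_reads <- function(rs, ids) {
  bl <- merge(rs$blocks[read_id %in% ids],
              rs$reads[, c("read_id", "chrom", "strand")], by = "read_id")
  reads_u <- unique(bl$read_id)
  memb <- integer(length(reads_u))
  names(memb) <- reads_u
  next_comp <- 0L
  for (grp in split(bl, paste(bl$chrom, bl$strand))) {
    ir <- IRanges::IRanges(grp$start + 1L, grp$end)
    cov <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, cov, minoverlap = 1L)
    ridx <- match(grp$read_id[S4Vectors::queryHits(hit)], unique(grp$read_id))
    cidx <- S4Vectors::subjectHits(hit)
    nr <- length(unique(grp$read_id))
    comp <- components_of(nr + length(cov), ridx, nr + cidx)
    memb[unique(grp$read_id)] <- next_comp + match(comp[seq_len(nr)],
                                                   unique(comp[seq_len(nr)]))
    next_comp <- max(memb)
  }
  data.table::data.table(read_id = names(memb),
                         locus_id = sprintf("L%05d", memb))
}

assign_reads_to_genes <- function(rs, annotation) {
  gb <- merge(annotation$blocks,
              annotation$transcripts[, c("transcript_id", "gene_id", "chrom",
                                         "strand")],
              by = "transcript_id")
  gb[is.na(gene_id), gene_id := transcript_id]
  # gene exonic footprint
  foot <- gb[, {
    r <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
    list(start = IRanges::start(r) - 1L, end = IRanges::end(r))
  }, by = c("gene_id", "chrom", "strand")]
  rb <- merge(rs$blocks, rs$reads[, c("read_id", "chrom", "strand")],
              by = "read_id")
  data.table::setkey(foot, chrom, strand, start, end)
  ov <- data.table::foverlaps(rb, foot,
                              by.x = c("chrom", "strand", "start", "end"),
                              type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(NULL)
  ov[, olap := pmin(end, i.end) - pmax(start, i.start)]
  ov <- ov[olap > 0L]
  tot <- ov[, list(olap = sum(olap)), by = c("read_id", "gene_id")]
  data.table::setorder(tot, read_id, -olap, gene_id)
  best <- tot[, .SD[1L], by = read_id]
  data.table::data.table(read_id = best$read_id, locus_id = best$gene_id)
}

#' Tally read start/end genomic locations per locus
#'
#' For `side = "start5"` only cap-captured reads are tallied (cap-enriched
#' libraries are the only trustworthy evidence for 5' ends); for
#' `side = "end3"` all reads count. The position is the transcription-order
#' 5'-most (start5) or 3'-most (end3) aligned genomic base of the read.
#'
#' @param loci output of [build_loci()].
#' @param rs a [read_set()].
#' @param side `"start5"` or `"end3"`.
#' @return an `end_tally`: data.table with one row per (locus, position),
#'   columns locus_id, side, chrom, strand, pos, k. Loci with no eligible
#'   read simply have no rows.
#' @export
tally_ends <- function(loci, rs, side = c("start5", "end3")) {
  side <- match.arg(side)
  reads <- merge(rs$reads, loci[, c("read_id", "locus_id")], by = "read_id")
  if (side == "start5") reads <- reads[cap == TRUE]
  if (nrow(reads) == 0L) {
    return(data.table::data.table(locus_id = character(), side = character(),
                                  chrom = character(), strand = character(),
                                  pos = integer(), k = integer()))
  }
  pos <- if (side == "start5") {
    ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  } else {
    ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  }
  t <- data.table::data.table(locus_id = reads$locus_id, side = side,
                              chrom = reads$chrom, strand = reads$strand,
                              pos = pos)
  out <- t[, list(k = .N), by = c("locus_id", "side", "chrom", "strand", "pos")]
  data.table::setkey(out, locus_id, pos)
  out[]
}

#' Remove off-priming 3' end locations
#'
#' A 3'-end location is flagged as genomically templated off-priming when at
#' least `offprime_min_A` of the `offprime_window` genomic nucleotides
#' immediately downstream (transcription order) are adenosine on the
#' transcribed strand. Flagged positions are removed and the removed rows
#' kept in the `"removed"` attribute (with their read counts), so that
#' removed + retained reads equal the input.
#'
#' @param tally an `end_tally` for side `"end3"` from [tally_ends()].
#' @param genome a `DNAStringSet`.
#' @param params a [pipeline_params()].
#' @return the filtered tally; attributes `removed` (flagged rows) and
#'   `removed_reads` (total reads discarded).
#' @export
flag_off_priming <- function(tally, genome, params = pipeline_params()) {
  if (nrow(tally) && !all(tally$side == "end3"))
    stopf("off-priming filtering applies to 3' end tallies only")
  if (nrow(tally) == 0L) {
    attr(tally, "removed") <- tally
    attr(tally, "removed_reads") <- 0L
    return(tally)
  }
  w <- params$offprime_window
  lens <- genome_lengths(genome)[tally$chrom]
  plus <- tally$strand == "+"
  s <- ifelse(plus, tally$pos + 1L, pmax(tally$pos - w, 0L))
  e <- ifelse(plus, pmin(tally$pos + 1L + w, lens), tally$pos)
  avail <- pmax(e - s, 0L)
  seqs <- genome_fetch(genome, tally$chrom, pmin(s, e), e)
  base <- ifelse(plus, "A", "T")  # transcribed-strand A
  nA <- integer(nrow(tally))
  nz <- avail > 0L
  if (any(nz))
    nA[nz] <- Biostrings::letterFrequency(
      Biostrings::DNAStringSet(seqs[nz]), "A")[, 1L] * plus[nz] +
      Biostrings::letterFrequency(
        Biostrings::DNAStringSet(seqs[nz]), "T")[, 1L] * (!plus[nz])
  thr <- params$offprime_min_A * avail / w  # prorated at chromosome edges
  flagged <- nz & nA >= thr
  out <- tally[!flagged]
  attr(out, "removed") <- tally[flagged]
  attr(out, "removed_reads") <- sum(tally$k[flagged])
  out
}

#' Binomial significant end calls
#'
#' Within each locus and side, with m reads distributed over n distinct
#' start/end locations and equal-probability null p = 1/n, the probability
#' of observing k reads at one location is the binomial point mass
#' Pr(k; m, p). A location is a significant call iff k > m/n and
#' Pr < `end_alpha`. With n = 1 no location can be significant. The default
#' evaluates the point mass exactly as the method defines it; `tail = TRUE`
#' computes the upper-tail P(X >= k) instead for sensitivity analysis.
#'
#' @param tally an `end_tally` from [tally_ends()] (after
#'   [flag_off_priming()] for 3' ends).
#' @param params a [pipeline_params()].
#' @param tail use the upper-tail probability instead of the point mass.
#' @return data.table of significant calls: locus_id, side, chrom, strand,
#'   pos, k, m, n, pr, status = "significant".
#' @export
binomial_calls <- function(tally, params = pipeline_params(), tail = FALSE) {
  if (nrow(tally) == 0L) return(empty_calls())
  t <- data.table::copy(tally)
  t[, `:=`(m = sum(k), n = .N), by = c("locus_id", "side")]
  t[, pr := if (tail) stats::pbinom(k - 1L, m, 1 / n, lower.tail = FALSE)
            else stats::dbinom(k, m, 1 / n)]
  out <- t[k > m / n & pr < params$end_alpha]
  if (nrow(out) == 0L) return(empty_calls())
  out[, `:=`(status = "significant", window_support = NA_integer_)]
  out[]
}

empty_calls <- function() {
  data.table::data.table(locus_id = character(), side = character(),
                         chrom = character(), strand = character(),
                         pos = integer(), k = integer(), m = integer(),
                         n = integer(), pr = numeric(), status = character(),
                         window_support = integer())
}

#' Sliding-window supported end calls
#'
#' For loci where the binomial test finds nothing, a location is a
#' candidate when the read count summed over the window
#' `[pos - h, pos + h]` (h = `end_window_halfwidth`) reaches
#' `end_min_reads`. Candidates within h nt of each other are collapsed to
#' the one with the highest own count, ties to the transcription-order
#' 5'-most, so reported calls are at least h + 1 nt apart.
#'
#' @param tally an `end_tally`.
#' @param params a [pipeline_params()].
#' @param exclude_loci loci that already have significant calls on this
#'   side (they are skipped).
#' @return data.table of supported calls in the same layout as
#'   [binomial_calls()], with `window_support` filled in.
#' @export
window_support_calls <- function(tally, params = pipeline_params(),
                                 exclude_loci = character()) {
  if (nrow(tally) == 0L) return(empty_calls())
  h <- params$end_window_halfwidth
  minr <- params$end_min_reads
  t <- tally[!locus_id %in% exclude_loci]
  if (nrow(t) == 0L) return(empty_calls())
  t <- data.table::copy(t)
  data.table::setkey(t, locus_id, pos)
  calls <- t[, {
    wsum <- vapply(pos, function(p) sum(k[pos >= p - h & pos <= p + h]),
                   numeric(1L))
    cand <- which(wsum >= minr)
    if (length(cand) == 0L) {
      NULL
    } else {
      cp <- pos[cand]
      grp <- cumsum(c(1L, diff(cp) > h))
      pick <- vapply(split(seq_along(cand), grp), function(ii) {
        kk <- k[cand[ii]]
        best <- ii[kk == max(kk)]
        # 5'-most in transcription order
        if (strand[1L] == "+") best[1L] else best[length(best)]
      }, integer(1L))
      list(pos = cp[pick], k = k[cand[pick]], m = sum(k), n = .N,
           window_support = as.integer(wsum[cand[pick]]))
    }
  }, by = c("locus_id", "side", "chrom", "strand")]
  if (nrow(calls) == 0L) return(empty_calls())
  calls[, `:=`(pr = NA_real_, status = "supported")]
  data.table::setcolorder(calls, names(empty_calls()))
  calls[]
}

#' Stratified end calling
#'
#' Runs [binomial_calls()] first; loci with no significant call on a side
#' fall through to [window_support_calls()]. This makes the stratification
#' boundary emergent from the data rather than a fixed read-count cut.
#'
#' @inheritParams binomial_calls
#' @return combined calls table.
#' @export
call_ends <- function(tally, params = pipeline_params(), tail = FALSE) {
  sig <- binomial_calls(tally, params, tail = tail)
  sup <- window_support_calls(tally, params,
                              exclude_loci = unique(sig$locus_id))
  data.table::rbindlist(list(sig, sup))
}

#' High-confidence end regions
#'
#' Places a `[pos - h, pos + h]` window (h = `region_halfwidth`, inclusive
#' on both edges; stored half-open as `[pos - h, pos + h + 1)`) around each
#' call, clipped to the chromosome. Overlapping regions are kept as is.
#'
#' @param calls calls from [call_ends()] (or either caller individually).
#' @param genome a `DNAStringSet`.
#' @param params a [pipeline_params()].
#' @return data.table with locus_id, side, chrom, strand, pos,
#'   region_start, region_end.
#' @export
make_regions <- function(calls, genome, params = pipeline_params()) {
  h <- params$region_halfwidth
  lens <- genome_lengths(genome)[calls$chrom]
  data.table::data.table(
    locus_id = calls$locus_id, side = calls$side, chrom = calls$chrom,
    strand = calls$strand, pos = calls$pos,
    region_start = pmax(calls$pos - h, 0L),
    region_end = pmin(calls$pos + h + 1L, as.integer(lens)))
}

#' Summarise end detection per side
#'
#' Reports, for one side, the reduction achieved by the binomial test:
#' total read start/end locations, the subset belonging to loci with at
#' least one significant call, significant call and locus counts, and the
#' mean numbers of locations and significant calls per such locus (rounded
#' half-up to 2 decimals, via [mean_calls_per_locus()]).
#'
#' @param calls calls from [call_ends()].
#' @param tally the tally the calls were made from.
#' @param removed_reads reads removed by off-priming (0 for 5' side).
#' @return one-row data.table per side present in the input.
#' @export
summarize_end_detection <- function(calls, tally, removed_reads = 0L) {
  sides <- unique(c(calls$side, tally$side))
  out <- lapply(sides, function(sd) {
    t <- tally[side == sd]
    cs <- calls[side == sd & status == "significant"]
    sig_loci <- unique(cs$locus_id)
    t_sig <- t[locus_id %in% sig_loci]
    data.table::data.table(
      side = sd,
      total_locations = nrow(t),
      locations_in_significant_loci = nrow(t_sig),
      significant_calls = nrow(cs),
      loci_with_calls = length(sig_loci),
      mean_locations_per_locus = mean_calls_per_locus(nrow(t_sig),
                                                      length(sig_loci)),
      mean_significant_per_locus = mean_calls_per_locus(nrow(cs),
                                                        length(sig_loci)),
      removed_offpriming_reads = removed_reads,
      retained_locations = nrow(t))
  })
  data.table::rbindlist(out)
}

#' Summary arithmetic helpers
#'
#' The rounding conventions of the pipeline's printed summaries: per-locus
#' means are rounded half-up to 2 decimals; retention percentages half-up
#' to 2 decimals; reduction percentages half-up to whole percent.
#'
#' @param n_calls,n_loci call and locus counts.
#' @return `mean_calls_per_locus`: the 2-decimal mean (0 when `n_loci` is 0).
#' @export
mean_calls_per_locus <- function(n_calls, n_loci) {
  if (n_loci == 0L) return(0)
  round_half_up(n_calls / n_loci, 2L)
}

#' @rdname mean_calls_per_locus
#' @param retained,total retained and total counts.
#' @export
retention_percent <- function(retained, total) {
  round_half_up(100 * retained / total, 2L)
}

#' @rdname mean_calls_per_locus
#' @param before,after counts before and after filtering.
#' @export
reduction_percent <- function(before, after) {
  round_half_up(100 * (before - after) / before, 0L)
}

#' @rdname mean_calls_per_locus
#' @param removed count removed.
#' @export
retained_after_removal <- function(total, removed) {
  total - removed
}
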