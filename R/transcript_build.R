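#' Collapse reads into unique transcripts
#'
#' Reads are grouped iff they share chromosome, strand, splice-junction
#' chain, start and end exactly (zero-nt wobble), so models differing by a
#' single nucleotide at either UTR stay distinct. Transcript ids are
#' deterministic (genome order + serial) and `support` is the group size.
#'
#' @param rs a [read_set()].
#' @param id_prefix prefix for generated transcript ids (default "T").
#' @param source source tag stored on the models (default "isoseq").
#' @return a [transcript_set()]; the `read_map` attribute maps each read to
#'   its transcript.
#' @export
collapse_exact <- function(rs, id_prefix = "T", source = "isoseq") {
  bl <- rs$blocks
  chain <- bl[, list(chain = paste(sprintf("%d-%d", end[-.N], start[-1L]),
                                   collapse = ";"),
                     start = min(start), end = max(end)), by = read_id]
  chain[is.na(chain) | chain == "NA-NA", chain := ""]
  g <- merge(chain, rs$reads[, c("read_id", "chrom", "strand")],
             by = "read_id", sort = FALSE)
  grp <- g[, list(support = .N, rep_read = sort(read_id)[1L]),
           by = c("chrom", "strand", "chain", "start", "end")]
  data.table::setorder(grp, chrom, start, end, chain)
  grp[, transcript_id := sprintf("%s%06d", id_prefix, seq_len(.N))]
  nb <- rs$reads$n_blocks[match(grp$rep_read, rs$reads$read_id)]
  rep_blocks <- bl[data.table::data.table(read_id = grp$rep_read),
                   on = "read_id"]
  rep_blocks[, transcript_id := rep(grp$transcript_id, nb)]
  tr <- data.table::data.table(transcript_id = grp$transcript_id,
                               chrom = grp$chrom, strand = grp$strand,
                               source = source, support = grp$support)
  ts <- transcript_set(tr, rep_blocks[, c("transcript_id", "start", "end")])
  map <- merge(g, grp, by = c("chrom", "strand", "chain", "start", "end"))
  attr(ts, "read_map") <- map[, c("read_id", "transcript_id")]
  ts
}

#' Filter transcripts by high-confidence splice junctions
#'
#' A model is kept iff every junction of its chain is in the
#' high-confidence set; mono-exon models always pass.
#'
#' @param ts a [transcript_set()].
#' @param hc_keys character vector of high-confidence junction keys (the
#'   `key` column of [call_high_confidence()]'s `hc == TRUE` rows).
#' @return list with `kept` and `removed` transcript sets; removed models'
#'   offending junctions are in the `reasons` attribute of `removed`.
#' @export
filter_by_sjs <- function(ts, hc_keys) {
  j <- ts_junctions(ts)
  bad <- j[!key %in% hc_keys]
  bad_ids <- unique(bad$transcript_id)
  kept <- ts_subset(ts, setdiff(ts$transcripts$transcript_id, bad_ids))
  removed <- ts_subset(ts, bad_ids)
  attr(removed, "reasons") <- bad[, list(reason = paste0("sj:", key[1L])),
                                  by = transcript_id]
  list(kept = kept, removed = removed)
}

#' Filter transcripts by high-confidence end regions
#'
#' A model is kept iff its transcription-order start lies inside a start5
#' region and its end inside an end3 region of the same chromosome and
#' strand (regions are inclusive windows around called ends). Removed
#' models carry reason `no_tss`, `no_tes` or `neither`.
#'
#' @param ts a [transcript_set()].
#' @param regions regions from [make_regions()] (both sides together).
#' @return list with `kept` and `removed`; reasons attached to `removed`.
#' @export
filter_by_ends <- function(ts, regions) {
  ends <- ts_tx_ends(ts)
  in_region <- function(pos_col, want_side) {
    out <- rep(FALSE, nrow(ends))
    r <- data.table::copy(regions[side == want_side])
    if (nrow(r) == 0L) return(out)
    q <- data.table::data.table(idx = seq_len(nrow(ends)),
                                chrom = ends$chrom, strand = ends$strand,
                                s = ends[[pos_col]], e = ends[[pos_col]])
    data.table::setkey(r, chrom, strand, region_start, region_end)
    hit <- data.table::foverlaps(q, r,
                                 by.x = c("chrom", "strand", "s", "e"),
                                 by.y = c("chrom", "strand", "region_start",
                                          "region_end"),
                                 type = "within", nomatch = NULL)
    hit <- hit[s < region_end]  # stored half-open on the right
    out[unique(hit$idx)] <- TRUE
    out
  }
  has_tss <- in_region("tx_start", "start5")
  has_tes <- in_region("tx_end", "end3")
  keep <- has_tss & has_tes
  reason <- ifelse(keep, NA_character_,
                   ifelse(!has_tss & !has_tes, "neither",
                          ifelse(!has_tss, "no_tss", "no_tes")))
  kept <- ts_subset(ts, ends$transcript_id[keep])
  removed <- ts_subset(ts, ends$transcript_id[!keep])
  attr(removed, "reasons") <- data.table::data.table(
    transcript_id = ends$transcript_id[!keep], reason = reason[!keep])
  list(kept = kept, removed = removed)
}

#' Rescue removed transcripts by annotation overlap
#'
#' A model removed by end filtering is rescued when at least
#' `params$rescue_overlap` of its exonic length overlaps the exonic
#' footprint of some same-strand annotated transcript. With
#' `locus_extend = TRUE` (the default), all removed models of a locus
#' containing a rescued model are rescued with it.
#'
#' @param removed a [transcript_set()] of removed models.
#' @param annotation a [transcript_set()] of annotated transcripts.
#' @param params a [pipeline_params()].
#' @param locus_extend extend rescue to whole loci (default TRUE).
#' @return a [transcript_set()] of rescued models.
#' @export
rescue_by_annotation <- function(removed, annotation,
                                 params = pipeline_params(),
                                 locus_extend = TRUE) {
  if (nrow(removed$transcripts) == 0L || nrow(annotation$transcripts) == 0L)
    return(ts_subset(removed, character()))
  ov <- pairwise_exonic_overlap(removed, annotation)
  len <- ts_exonic_length(removed)
  ov <- merge(ov, len, by.x = "a_id", by.y = "transcript_id")
  hit <- ov[olap >= params$rescue_overlap * exonic_len, unique(a_id)]
  if (locus_extend && length(hit)) {
    loc <- model_loci(removed)
    hit_loc <- unique(loc[transcript_id %in% hit, locus])
    hit <- loc[locus %in% hit_loc, transcript_id]
  }
  ts_subset(removed, hit)
}

# summed exonic overlap between each pair of same-strand models from two sets
pairwise_exonic_overlap <- function(a, b) {
  ab <- merge(a$blocks, a$transcripts[, c("transcript_id", "chrom", "strand")],
              by = "transcript_id")
  bb <- merge(b$blocks, b$transcripts[, c("transcript_id", "chrom", "strand")],
              by = "transcript_id")
  data.table::setnames(ab, "transcript_id", "a_id")
  data.table::setnames(bb, "transcript_id", "b_id")
  data.table::setkey(bb, chrom, strand, start, end)
  ov <- data.table::foverlaps(ab, bb, by.x = c("chrom", "strand", "start", "end"),
                              type = "any", nomatch = NULL)
  ov[, olap := pmin(end, i.end) - pmax(start, i.start)]
  ov <- ov[olap > 0L]
  ov[, list(olap = sum(olap)), by = c("a_id", "b_id")]
}

# single-linkage loci over models (same-strand exonic overlap)
model_loci <- function(ts) {
  bl <- merge(ts$blocks, ts$transcripts[, c("transcript_id", "chrom", "strand")],
              by = "transcript_id")
  ids <- unique(bl$transcript_id)
  memb <- integer(length(ids)); names(memb) <- ids
  nxt <- 0L
  for (grp in split(bl, paste(bl$chrom, bl$strand))) {
    ir <- IRanges::IRanges(grp$start + 1L, grp$end)
    cov <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, cov, minoverlap = 1L)
    u <- unique(grp$transcript_id)
    comp <- components_of(length(u) + length(cov),
                          match(grp$transcript_id[S4Vectors::queryHits(hit)], u),
                          length(u) + S4Vectors::subjectHits(hit))
    memb[u] <- nxt + match(comp[seq_along(u)], unique(comp[seq_along(u)]))
    nxt <- max(memb)
  }
  data.table::data.table(transcript_id = names(memb), locus = memb)
}

#' High-level transcript collapse
#'
#' Greedy grouping seeded by descending support (ties: longest span, then
#' leftmost): a model joins a group iff it has the seed's splice-junction
#' chain and both ends within `params$collapse_wobble_high` nt of the
#' seed's. Mono-exon models group under the same end rule plus at least
#' 1 nt of overlap. The representative keeps the seed's coordinates with
#' support summed, so junction variants as small as NAGNAG acceptor shifts
#' are preserved as separate models.
#'
#' @param ts a [transcript_set()].
#' @param params a [pipeline_params()].
#' @return a collapsed [transcript_set()].
#' @export
collapse_high_level <- function(ts, params = pipeline_params()) {
  w <- params$collapse_wobble_high
  tr <- merge(ts$transcripts, ts_chain(ts)[, c("transcript_id", "chain")],
              by = "transcript_id")
  data.table::setorder(tr, chrom, strand, chain, -support, start, end)
  tr[, span := end - start]
  keep_ids <- character(0L)
  add_support <- list()
  for (grp in split(tr, paste(tr$chrom, tr$strand, tr$chain), drop = TRUE)) {
    o <- order(-grp$support, -grp$span, grp$start)
    grp <- grp[o]
    n <- nrow(grp)
    assigned <- rep(NA_integer_, n)
    mono <- grp$chain[1L] == ""
    for (i in seq_len(n)) {
      if (!is.na(assigned[i])) next
      assigned[i] <- i
      if (i < n) {
        js <- which(is.na(assigned))
        ok <- abs(grp$start[js] - grp$start[i]) <= w &
          abs(grp$end[js] - grp$end[i]) <= w
        if (mono)
          ok <- ok & pmin(grp$end[js], grp$end[i]) -
            pmax(grp$start[js], grp$start[i]) >= 1L
        assigned[js[ok]] <- i
      }
    }
    seeds <- unique(assigned)
    keep_ids <- c(keep_ids, grp$transcript_id[seeds])
    supp <- tapply(grp$support, assigned, sum)
    add_support <- c(add_support, list(data.table::data.table(
      transcript_id = grp$transcript_id[as.integer(names(supp))],
      support = as.integer(supp))))
  }
  out <- ts_subset(ts, keep_ids)
  supp <- data.table::rbindlist(add_support)
  out$transcripts[supp, support := i.support, on = "transcript_id"]
  out
}

#' Transcript filtering report
#'
#' Bookkeeping for the collapse-filter-rescue pipeline stage: input,
#' removed-by-SJ, removed-by-ends, rescued and retained counts partition
#' the input, and mono-exon models removed by end filtering are tallied
#' separately.
#'
#' @param input,sj_removed,end_removed,rescued,retained transcript sets
#'   from the respective stages.
#' @return a `filter_report` (named list of counts plus per-transcript
#'   reason codes).
#' @export
filter_report <- function(input, sj_removed, end_removed, rescued, retained) {
  n <- function(ts) nrow(ts$transcripts)
  mono_removed <- sum(end_removed$transcripts$n_blocks == 1L)
  mono_input <- sum(input$transcripts$n_blocks == 1L)
  reasons <- data.table::rbindlist(list(
    attr(sj_removed, "reasons"),
    attr(end_removed, "reasons")), use.names = TRUE, fill = TRUE)
  if (n(rescued) > 0L)
    reasons <- reasons[!transcript_id %in% rescued$transcripts$transcript_id]
  rep <- list(input = n(input),
              removed_by_sj = n(sj_removed),
              removed_by_ends = n(end_removed),
              rescued = n(rescued),
              retained = n(retained),
              mono_exon_input = mono_input,
              mono_exon_removed_by_ends = mono_removed,
              reasons = reasons)
  stopifnot(rep$input == rep$retained + rep$removed_by_sj +
              rep$removed_by_ends - rep$rescued)
  class(rep) <- "filter_report"
  rep
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("transcript filter report:\n",
                     "  input                %d\n",
                     "  removed by SJ filter %d\n",
                     "  removed by end filter %d (mono-exon: %d of %d)\n",
                     "  rescued by annotation %d\n",
                     "  retained             %d\n"),
              x$input, x$removed_by_sj, x$removed_by_ends,
              x$mono_exon_removed_by_ends, x$mono_exon_input,
              x$rescued, x$retained))
  invisible(x)
}
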