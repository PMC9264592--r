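#' Select candidate transcripts carrying novel splice junctions
#'
#' A candidate model is selected iff at least one junction of its chain is
#' absent from the base junction-key set. Selection is sequential across
#' candidate RTDs: the returned key set extends the base with the accepted
#' models' junctions, so a later candidate repeating a junction admitted in
#' an earlier round is not selected again.
#'
#' @param candidate a [transcript_set()] (e.g. a short-read RTD).
#' @param base_sj_keys character vector of junction keys already in the
#'   growing RTD.
#' @return list with `models` (selected subset) and `sj_keys` (base keys
#'   extended by the selected models' junctions).
#' @export
novel_sj_transcripts <- function(candidate, base_sj_keys) {
  j <- ts_junctions(candidate)
  sel <- unique(j[!key %in% base_sj_keys, transcript_id])
  models <- ts_subset(candidate, sel)
  new_keys <- unique(c(base_sj_keys, ts_junctions(models)$key))
  list(models = models, sj_keys = new_keys)
}

#' Select candidate transcripts covering novel loci
#'
#' A candidate model is selected iff its span overlaps no base-model span
#' on the same strand (strict zero overlap; antisense-only overlap counts
#' as novel).
#'
#' @param candidate,base [transcript_set()] objects.
#' @return the selected subset of `candidate`.
#' @export
novel_locus_transcripts <- function(candidate, base) {
  ct <- candidate$transcripts
  bt <- data.table::copy(base$transcripts[, c("chrom", "strand", "start", "end")])
  if (nrow(bt) == 0L) return(candidate)
  q <- data.table::data.table(idx = seq_len(nrow(ct)), chrom = ct$chrom,
                              strand = ct$strand, s = ct$start,
                              e = ct$end - 1L)
  bt[, end1 := end - 1L]
  data.table::setkey(bt, chrom, strand, start, end1)
  hit <- data.table::foverlaps(q, bt, by.x = c("chrom", "strand", "s", "e"),
                               by.y = c("chrom", "strand", "start", "end1"),
                               type = "any", nomatch = NULL)
  ts_subset(candidate, ct$transcript_id[setdiff(q$idx, hit$idx)])
}

#' Merge additions into the primary (long-read) RTD
#'
#' The primary RTD holds end-coordinate priority (its models are capped and
#' authoritative for TSS, SJ and TES); an addition is absorbed iff some
#' primary model has the identical splice-junction chain and both ends
#' within `params$collapse_wobble_high` nt (mono-exon additions also need
#' at least 1 nt of overlap). Absorbed additions contribute support only;
#' unabsorbed additions become new models keeping their source tag. No
#' primary model's coordinates are altered.
#'
#' @param primary a [transcript_set()] (the capped long-read RTD).
#' @param additions a [transcript_set()] of pre-filtered candidates (from
#'   [novel_sj_transcripts()] / [novel_locus_transcripts()]).
#' @param params a [pipeline_params()].
#' @return the merged [transcript_set()]; attribute `provenance` summarises
#'   models contributed and absorbed per source.
#' @export
merge_rtds <- function(primary, additions, params = pipeline_params()) {
  if (nrow(additions$transcripts) == 0L) {
    out <- primary
    attr(out, "provenance") <- provenance_table(primary$transcripts$source,
                                                character())
    return(out)
  }
  w <- params$collapse_wobble_high
  pc <- merge(ts_chain(primary),
              primary$transcripts[, c("transcript_id", "start", "end")],
              by = "transcript_id")
  ac <- merge(ts_chain(additions),
              additions$transcripts[, c("transcript_id", "start", "end")],
              by = "transcript_id")
  cand <- merge(ac, pc, by = c("chrom", "strand", "chain"),
                suffixes = c("", ".p"), allow.cartesian = TRUE)
  cand <- cand[abs(start - start.p) <= w & abs(end - end.p) <= w]
  cand[chain == "", ok := pmin(end, end.p) - pmax(start, start.p) >= 1L]
  cand <- cand[chain != "" | ok == TRUE]
  absorbed <- unique(cand$transcript_id)
  new_ids <- setdiff(additions$transcripts$transcript_id, absorbed)
  newts <- ts_subset(additions, new_ids)
  dup <- intersect(newts$transcripts$transcript_id,
                   primary$transcripts$transcript_id)
  if (length(dup)) {
    message(sprintf("renaming %d duplicate transcript id(s) with source suffix",
                    length(dup)))
    old <- newts$transcripts$transcript_id
    new <- ifelse(old %in% dup,
                  paste(old, newts$transcripts$source, sep = "."), old)
    newts$transcripts[, transcript_id := new]
    newts$blocks[, transcript_id := new[match(transcript_id, old)]]
  }
  out <- ts_bind(primary, newts)
  attr(out, "provenance") <- provenance_table(
    c(primary$transcripts$source, newts$transcripts$source),
    additions$transcripts$source[additions$transcripts$transcript_id %in% absorbed])
  out
}

provenance_table <- function(model_sources, absorbed_sources) {
  m <- table(model_sources)
  a <- table(absorbed_sources)
  src <- union(names(m), names(a))
  mm <- as.integer(m[src]); mm[is.na(mm)] <- 0L
  aa <- as.integer(a[src]); aa[is.na(aa)] <- 0L
  data.table::data.table(source = src, models = mm, absorbed = aa)
}

#' Build a merged RTD from a primary set and candidate RTDs
#'
#' Convenience wrapper running the sequential novel-junction extraction
#' over the candidate RTDs (in the given priority order), the novel-locus
#' extraction for candidates flagged for it, and the final merge.
#'
#' @param primary the long-read [transcript_set()].
#' @param candidates named list of candidate [transcript_set()]s, highest
#'   priority first.
#' @param novel_locus_from names of candidates whose novel-locus
#'   transcripts are also taken (typically the reference annotation).
#' @param params a [pipeline_params()].
#' @return the merged RTD with provenance attribute.
#' @export
build_rtd <- function(primary, candidates, novel_locus_from = character(),
                      params = pipeline_params()) {
  keys <- unique(ts_junctions(primary)$key)
  picked <- list()
  for (nm in names(candidates)) {
    res <- novel_sj_transcripts(candidates[[nm]], keys)
    keys <- res$sj_keys
    picked[[nm]] <- res$models
    if (nm %in% novel_locus_from) {
      nl <- novel_locus_transcripts(candidates[[nm]], primary)
      extra <- setdiff(nl$transcripts$transcript_id,
                       picked[[nm]]$transcripts$transcript_id)
      picked[[nm]] <- ts_bind(picked[[nm]], ts_subset(candidates[[nm]], extra))
    }
  }
  additions <- Reduce(ts_bind, picked,
                      ts_subset(primary, character()))
  merge_rtds(primary, additions, params)
}
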