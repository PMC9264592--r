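#' Run the full curation pipeline
#'
#' Chains the stages of long-read transcriptome curation: junction-evidence
#' extraction and high-confidence junction calling; locus building and
#' stratified end calling (binomial first, sliding window for loci without
#' significant calls) with off-priming removal on the 3' side; exact
#' collapse of reads to unique transcripts; SJ and end-region filtering
#' with optional annotation rescue; and the high-level 50-nt collapse.
#'
#' @param rs a [read_set()].
#' @param genome a `DNAStringSet`.
#' @param params a [pipeline_params()].
#' @param annotation optional [transcript_set()] used for rescue of models
#'   removed by end filtering (no rescue when NULL).
#' @return list with components `evidence`, `hc` (junction calls), `loci`,
#'   `tally5`, `tally3` (off-priming filtered, with removal attributes),
#'   `calls`, `regions`, `collapsed` (exact-collapse models), `transcripts`
#'   (the final high-level set) and `report` (a [filter_report()]).
#' @export
curate_transcriptome <- function(rs, genome, params = pipeline_params(),
                                 annotation = NULL) {
  ev <- extract_junction_evidence(rs, genome, params)
  hc <- call_high_confidence(ev, params)
  loci <- build_loci(rs)
  t5 <- tally_ends(loci, rs, "start5")
  t3 <- flag_off_priming(tally_ends(loci, rs, "end3"), genome, params)
  calls <- data.table::rbindlist(list(call_ends(t5, params),
                                      call_ends(t3, params)))
  regions <- make_regions(calls, genome, params)
  models <- collapse_exact(rs)
  f1 <- filter_by_sjs(models, hc[hc == TRUE, key])
  f2 <- filter_by_ends(f1$kept, regions)
  rescued <- if (!is.null(annotation)) {
    rescue_by_annotation(f2$removed, annotation, params)
  } else {
    ts_subset(f2$removed, character())
  }
  retained <- ts_bind(f2$kept, rescued)
  final <- collapse_high_level(retained, params)
  report <- filter_report(models, f1$removed, f2$removed, rescued, retained)
  list(evidence = ev, hc = hc, loci = loci, tally5 = t5, tally3 = t3,
       calls = calls, regions = regions, collapsed = models,
       transcripts = final, report = report)
}

#' Evaluate a pipeline run against simulation truth
#'
#' Computes the headline recovery metrics of a seeded simulation run:
#' high-confidence junction precision/recall, the rejection rate of
#' wandered junctions, dominant TSS/TES recall within the region tolerance,
#' and the rejection rate of off-primed 3' ends at flagged A-runs.
#'
#' @param run output of [curate_transcriptome()].
#' @param sim_reads output of [simulate_reads()] (reads + truth tables).
#' @param params the [pipeline_params()] of the run.
#' @return named list of metrics.
#' @export
evaluate_run <- function(run, sim_reads, params = pipeline_params()) {
  truth <- sim_reads$truth
  hc_keys <- run$hc[hc == TRUE, key]
  sj <- truth_eval(hc_keys, truth, type = "sj")
  endcalls <- run$calls[, c("chrom", "strand", "side", "pos")]
  ends5 <- truth_eval(endcalls[side == "start5"], truth, type = "ends",
                      tolerance = params$region_halfwidth)
  # restrict the truth to each side for side-wise recall
  t5 <- truth; t5$ends <- truth$ends[side == "start5"]
  t3 <- truth; t3$ends <- truth$ends[side == "end3"]
  ends5 <- truth_eval(endcalls[side == "start5"], t5, type = "ends",
                      tolerance = params$region_halfwidth)
  ends3 <- truth_eval(endcalls[side == "end3"], t3, type = "ends",
                      tolerance = params$region_halfwidth)
  # wandered junctions present in the evidence that were rejected
  wkeys <- unique(stats::na.omit(sim_reads$truth_reads$wander_key_shifted))
  wkeys <- wkeys[wkeys %in% run$hc$key]
  wander_rej <- if (length(wkeys)) mean(!wkeys %in% hc_keys) else NA_real_
  # off-primed end positions that reached the 3' tally and were flagged
  removed <- attr(run$tally3, "removed")
  offp <- sim_reads$truth_reads[offprimed == TRUE]
  off_rej <- NA_real_
  if (nrow(offp)) {
    ends <- merge(offp[, c("read_id")],
                  rs_end_positions(sim_reads$reads), by = "read_id")
    tallied <- unique(ends[, c("chrom", "strand", "pos")])
    flagged <- unique(removed[, c("chrom", "strand", "pos")])
    present <- rbind(run$tally3[, c("chrom", "strand", "pos")], flagged)
    tallied <- tallied[present, on = c("chrom", "strand", "pos"),
                       nomatch = NULL]
    if (nrow(tallied))
      off_rej <- nrow(tallied[flagged, on = c("chrom", "strand", "pos"),
                              nomatch = NULL]) / nrow(tallied)
  }
  list(sj_precision = sj$precision, sj_recall = sj$recall,
       wander_rejection = wander_rej,
       tss_recall = ends5$recall, tes_recall = ends3$recall,
       tss_precision = ends5$precision, tes_precision = ends3$precision,
       offprime_rejection = off_rej,
       n = list(sj = sj$tp + sj$fn, sj_calls = length(hc_keys),
                wander = length(wkeys),
                tss = ends5$tp + ends5$fn, tes = ends3$tp + ends3$fn,
                offprime = if (nrow(offp)) nrow(tallied) else 0L))
}

# 3' end genomic position of every read
rs_end_positions <- function(rs) {
  r <- rs$reads
  data.table::data.table(read_id = r$read_id, chrom = r$chrom,
                         strand = r$strand,
                         pos = ifelse(r$strand == "+", r$end - 1L, r$start))
}
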