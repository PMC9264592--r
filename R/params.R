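#' Pipeline parameter set
#'
#' Collects every tunable constant of the curation pipeline in one list so
#' that a run is fully described by a genome, a read set and a parameter
#' object. All windows are in nucleotides on the genome.
#'
#' @param sj_window half-width of the exonic window around each splice
#'   junction from which mismatch offsets are recorded (default 30).
#' @param sj_clean_window near-junction window that must be mismatch-free in
#'   at least one read for a junction to be high confidence (default 10).
#' @param canonical_motifs intron motifs regarded as canonical, written
#'   donor-acceptor (default GT-AG, GC-AG, AT-AC).
#' @param pwm_threshold scaled position-weight-matrix score (0-100) above
#'   which a splice site is considered good (default 65).
#' @param end_alpha significance level for the binomial end-site test
#'   (default 0.05).
#' @param end_window_halfwidth half-width of the sliding window used for
#'   supported end calls, so the window spans `2*h + 1` nt (default 5).
#' @param end_min_reads minimum reads within the sliding window to call a
#'   supported end (default 2).
#' @param region_halfwidth half-width of the high-confidence TSS/TES region
#'   placed around each called end (default 50).
#' @param offprime_window number of genomic nucleotides downstream of a read
#'   3' end inspected for templated adenosines (default 10).
#' @param offprime_min_A minimum adenosines within `offprime_window` for an
#'   end to be flagged as off-priming (default 6).
#' @param collapse_wobble_exact maximum 5'/3' end difference for reads to be
#'   collapsed into one unique transcript (default 0).
#' @param collapse_wobble_high maximum end difference for the high-level
#'   transcript merge (default 50).
#' @param rescue_overlap minimum fraction of a removed model's exonic length
#'   that must overlap an annotated transcript for rescue (default 0.5).
#' @param gene_overlap overlap fraction (of either party) above which a model
#'   is assigned to a reference gene (default 0.3, strict greater-than).
#' @param motif_flank half-width of the flank extracted around sites for
#'   motif scanning (default 500).
#' @param nonstop_cds_slack maximum nt between CDS end and transcript end for
#'   a non-stop candidate (default 3, strict less-than).
#' @param nonstop_stop_window tail window searched for an in-frame stop codon
#'   (default 5).
#' @param nonstop_tes_gap minimum distance between the gene's most distal TES
#'   and the candidate's end (default 100, strict greater-than).
#' @param orf_min_codons minimum ORF length, in codons, for a transcript to
#'   count as protein coding (default 100).
#' @param rng_seed integer seed recorded with the run.
#'
#' @return an object of class `pipeline_params` (a validated named list).
#' @export
pipeline_params <- function(sj_window = 30L,
                            sj_clean_window = 10L,
                            canonical_motifs = c("GT-AG", "GC-AG", "AT-AC"),
                            pwm_threshold = 65,
                            end_alpha = 0.05,
                            end_window_halfwidth = 5L,
                            end_min_reads = 2L,
                            region_halfwidth = 50L,
                            offprime_window = 10L,
                            offprime_min_A = 6L,
                            collapse_wobble_exact = 0L,
                            collapse_wobble_high = 50L,
                            rescue_overlap = 0.5,
                            gene_overlap = 0.3,
                            motif_flank = 500L,
                            nonstop_cds_slack = 3L,
                            nonstop_stop_window = 5L,
                            nonstop_tes_gap = 100L,
                            orf_min_codons = 100L,
                            rng_seed = 1L) {
  p <- list(
    sj_window = as.integer(sj_window),
    sj_clean_window = as.integer(sj_clean_window),
    canonical_motifs = as.character(canonical_motifs),
    pwm_threshold = as.numeric(pwm_threshold),
    end_alpha = as.numeric(end_alpha),
    end_window_halfwidth = as.integer(end_window_halfwidth),
    end_min_reads = as.integer(end_min_reads),
    region_halfwidth = as.integer(region_halfwidth),
    offprime_window = as.integer(offprime_window),
    offprime_min_A = as.integer(offprime_min_A),
    collapse_wobble_exact = as.integer(collapse_wobble_exact),
    collapse_wobble_high = as.integer(collapse_wobble_high),
    rescue_overlap = as.numeric(rescue_overlap),
    gene_overlap = as.numeric(gene_overlap),
    motif_flank = as.integer(motif_flank),
    nonstop_cds_slack = as.integer(nonstop_cds_slack),
    nonstop_stop_window = as.integer(nonstop_stop_window),
    nonstop_tes_gap = as.integer(nonstop_tes_gap),
    orf_min_codons = as.integer(orf_min_codons),
    rng_seed = as.integer(rng_seed)
  )
  validate_params(p)
  class(p) <- "pipeline_params"
  p
}

validate_params <- function(p) {
  windows <- c("sj_window", "sj_clean_window", "end_window_halfwidth",
               "region_halfwidth", "offprime_window", "motif_flank")
  for (w in windows)
    if (!is.finite(p[[w]]) || p[[w]] <= 0L) stopf("parameter %s must be positive", w)
  for (f in c("rescue_overlap", "gene_overlap", "end_alpha"))
    if (!is.finite(p[[f]]) || p[[f]] <= 0 || p[[f]] > 1)
      stopf("parameter %s must be in (0, 1]", f)
  if (p$collapse_wobble_exact < 0L || p$collapse_wobble_high < 0L)
    stopf("collapse wobbles must be >= 0")
  if (!all(grepl("^[ACGT]{2}-[ACGT]{2}$", p$canonical_motifs)))
    stopf("canonical_motifs must look like 'GT-AG'")
  invisible(TRUE)
}

#' @rdname pipeline_params
#' @param path file path of a JSON parameter file.
#' @export
read_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_params, raw)
}

#' @rdname pipeline_params
#' @param params a `pipeline_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "pipeline_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.pipeline_params <- function(x, ...) {
  cat("curation pipeline parameters:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}

# motifs as stored internally (no hyphen): "GTAG" etc.
canonical_motif_keys <- function(params) {
  gsub("-", "", params$canonical_motifs, fixed = TRUE)
}
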