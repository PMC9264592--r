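#' Extract per-read mismatch evidence around splice junctions
#'
#' For every intron of every multi-exon read, records the read's mismatch
#' events (substitutions, insertions, deletions) that fall within
#' `params$sj_window` nucleotides of the junction on the exonic (aligned)
#' side, as offsets 1..window counted from the junction in transcription
#' order. Offsets are truncated at the edge of the adjacent exon; insertions
#' between two exonic bases take the offset of the base nearer the junction;
#' deletions contribute every exonic position of their genomic footprint.
#' The intron motif (first two + last two intronic bases on the transcribed
#' strand, e.g. "GTAG") is read from the genome.
#'
#' @param rs a [read_set()].
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param params a [pipeline_params()].
#' @return an object of class `junction_evidence`: a list with
#'   `junctions` (one row per distinct junction: key, chrom, strand,
#'   intron_start, intron_end, motif, support), `observations` (one row per
#'   read-junction pair: key, read_id, total60, near_clean counts) and
#'   `offsets` (long table key, read_id, side in up/down, offset).
#' @export
extract_junction_evidence <- function(rs, genome, params = pipeline_params()) {
  stopifnot(inherits(rs, "read_set"))
  W <- params$sj_window
  bl <- rs$blocks
  ji <- bl[, if (.N > 1L) list(up_start = start[-.N], intron_start = end[-.N],
                               intron_end = start[-1L], down_end = end[-1L]),
           by = read_id]
  if (nrow(ji) == 0L) {
    return(empty_evidence())
  }
  ji <- merge(ji, rs$reads[, c("read_id", "chrom", "strand")],
              by = "read_id", sort = FALSE)
  lens <- genome_lengths(genome)
  if (any(ji$intron_end > lens[ji$chrom]) | any(ji$intron_start < 0L))
    stopf("junction extends past chromosome end")
  ji[, key := junction_key(chrom, strand, intron_start, intron_end)]

  jx <- unique(ji[, c("key", "chrom", "strand", "intron_start", "intron_end")])
  first2 <- genome_fetch(genome, jx$chrom, jx$intron_start, jx$intron_start + 2L)
  last2 <- genome_fetch(genome, jx$chrom, pmax(jx$intron_end - 2L, jx$intron_start),
                        jx$intron_end)
  jx[, motif := ifelse(strand == "+",
                       paste0(first2, last2),
                       paste0(revcomp(last2), revcomp(first2)))]
  support <- ji[, list(support = .N), by = key]
  jx <- merge(jx, support, by = "key")

  offs <- junction_offsets(ji, rs$mismatches, W)
  obs <- ji[, c("read_id", "key")]
  counts <- offs[, list(total60 = .N,
                        near = sum(offset <= params$sj_clean_window)),
                 by = c("key", "read_id")]
  obs <- merge(obs, counts, by = c("key", "read_id"), all.x = TRUE)
  obs[is.na(total60), `:=`(total60 = 0L, near = 0L)]
  ev <- structure(list(junctions = jx, observations = obs, offsets = offs,
                       params = params),
                  class = "junction_evidence")
  collect_evidence(ev)
}

empty_evidence <- function(params = pipeline_params()) {
  with_key <- function(dt) {
    dt[, key := character()]
    data.table::setcolorder(dt, "key")
    dt
  }
  structure(list(
    junctions = with_key(data.table::data.table(
      chrom = character(), strand = character(),
      intron_start = integer(), intron_end = integer(), motif = character(),
      support = integer(), best_read = character(), best_total60 = integer())),
    observations = with_key(data.table::data.table(
      read_id = character(), total60 = integer(), near = integer())),
    offsets = with_key(data.table::data.table(
      read_id = character(), side = character(), offset = integer())),
    params = params), class = "junction_evidence")
}

# distinct (junction, read, side, offset) rows for all events within the
# exonic windows; ji has one row per read-junction instance
junction_offsets <- function(ji, mism, W) {
  # note: "key" is a reserved argument of the data.table() constructor
  empty <- data.table::data.table(read_id = character(), side = character(),
                                  offset = integer())
  empty[, key := character()]
  data.table::setcolorder(empty, c("key", "read_id", "side", "offset"))
  if (nrow(mism) == 0L) return(empty)
  win <- data.table::rbindlist(list(
    ji[, list(read_id, key, strand, edge = "left",
              intron_start, intron_end,
              lo = pmax(up_start, intron_start - W), hi = intron_start - 1L)],
    ji[, list(read_id, key, strand, edge = "right",
              intron_start, intron_end,
              lo = intron_end, hi = pmin(down_end, intron_end + W) - 1L)]))
  win <- win[hi >= lo]
  ev <- data.table::copy(mism)
  # closed-interval genomic footprint; insertions get both flanking bases
  # and are resolved to the one nearer the junction below
  ev[, fs := ifelse(kind == "ins", pos - 1L, pos)]
  ev[, fe := ifelse(kind == "del", pos + len - 1L, pos)]
  data.table::setkey(win, read_id, lo, hi)
  hit <- data.table::foverlaps(ev, win, by.x = c("read_id", "fs", "fe"),
                               type = "any", nomatch = NULL)
  if (nrow(hit) == 0L) return(empty)
  hit[, `:=`(gmin = pmax(fs, lo), gmax = pmin(fe, hi))]
  hit[kind == "ins" & edge == "left", gmin := gmax]
  hit[kind == "ins" & edge == "right", gmax := gmin]
  n <- hit$gmax - hit$gmin + 1L
  out <- hit[rep(seq_len(.N), n)]
  out[, g := gmin + unlist(lapply(n, seq_len)) - 1L]
  out[, offset := ifelse(edge == "left", intron_start - g, g - intron_end + 1L)]
  out[, side := ifelse((strand == "+") == (edge == "left"), "up", "down")]
  unique(out[, c("key", "read_id", "side", "offset")])
}

#' Select the best-aligned observation per junction
#'
#' The representative read of each junction is the observation with the
#' fewest mismatch positions in the 60-nt region around the junction, ties
#' broken by fewest positions within the near window (1..10 on both sides),
#' then by read id. Called automatically by [extract_junction_evidence()].
#'
#' @param ev a `junction_evidence` object.
#' @return `ev` with `best_read` and `best_total60` set on `junctions`.
#' @export
collect_evidence <- function(ev) {
  obs <- ev$observations
  if (nrow(obs) == 0L) return(ev)
  data.table::setorder(obs, key, total60, near, read_id)
  best <- obs[, list(best_read = read_id[1L], best_total60 = total60[1L]),
              by = key]
  ev$junctions <- merge(
    ev$junctions[, setdiff(names(ev$junctions),
                           c("best_read", "best_total60")), with = FALSE],
    best, by = "key")
  ev
}

best_offsets <- function(ev) {
  b <- data.table::data.table(read_id = ev$junctions$best_read)
  b[, key := ev$junctions$key]
  ev$offsets[b, on = c("key", "read_id"), nomatch = NULL]
}

#' Positional mismatch profile around junctions
#'
#' Counts, at each exonic position 1..`sj_window` from the junction, how
#' many junctions' best observations carry a mismatch there, with the
#' percentage over the junction subset. One side (transcription-order
#' upstream or downstream) per call.
#'
#' @param ev a `junction_evidence` object.
#' @param side `"up"` or `"down"`.
#' @param junctions optional character vector of junction keys restricting
#'   the profile (e.g. a high- or low-confidence subset).
#' @return data.table with columns position, count, percent.
#' @export
mismatch_profile <- function(ev, side = c("up", "down"), junctions = NULL) {
  side <- match.arg(side)
  keys <- junctions %||% ev$junctions$key
  if (length(keys) == 0L) stopf("empty junction subset")
  if (!all(keys %in% ev$junctions$key)) stopf("unknown junction key in subset")
  W <- ev$params$sj_window
  want_side <- side
  off <- best_offsets(ev)
  off <- off[key %in% keys][side == want_side]
  counts <- integer(W)
  if (nrow(off)) {
    tab <- off[, .N, by = offset]
    counts[tab$offset] <- tab$N
  }
  data.table::data.table(position = seq_len(W), count = counts,
                         percent = 100 * counts / length(keys))
}

#' Cumulative junction retention under near-junction mismatch filtering
#'
#' For each n in 1..`max_n`, a junction is removed if its best observation
#' has any mismatch at offset <= n on either side. The remaining percentage
#' is non-increasing in n.
#'
#' @param ev a `junction_evidence` object.
#' @param max_n largest window to evaluate (default `sj_window`).
#' @param junctions optional subset of junction keys.
#' @return data.table with columns n, junctions_removed, percent_remaining.
#' @export
retention_curve <- function(ev, max_n = NULL, junctions = NULL) {
  max_n <- max_n %||% ev$params$sj_window
  keys <- junctions %||% ev$junctions$key
  total <- length(keys)
  off <- best_offsets(ev)[key %in% keys]
  nearest <- if (nrow(off) == 0L) {
    data.table::data.table(nearest = integer())
  } else {
    off[, list(nearest = min(offset)), by = key]
  }
  removed <- vapply(seq_len(max_n), function(n) sum(nearest$nearest <= n),
                    integer(1L))
  data.table::data.table(
    n = seq_len(max_n),
    junctions_removed = removed,
    percent_remaining = if (total > 0L) 100 * (total - removed) / total else NA_real_)
}

#' Call high-confidence splice junctions
#'
#' A junction is high confidence iff (1) its intron motif is canonical and
#' (2) at least one supporting read has zero mismatch events at offsets
#' 1..`sj_clean_window` on both sides. Non-canonical motifs are checked
#' first, so a junction failing both carries reason `non_canonical`.
#'
#' @param ev a `junction_evidence` object.
#' @param params a [pipeline_params()] (defaults to the one stored in `ev`).
#' @return the junction table with logical `hc` and `reason` (`NA`,
#'   `"non_canonical"` or `"no_clean_read"`); the `hc`/rejected rows
#'   partition the input junction set.
#' @export
call_high_confidence <- function(ev, params = NULL) {
  params <- params %||% ev$params
  canon <- canonical_motif_keys(params)
  jx <- data.table::copy(ev$junctions)
  nearw <- params$sj_clean_window
  dirty <- ev$offsets[offset <= nearw, unique(paste(key, read_id))]
  obs <- ev$observations
  clean_keys <- unique(obs[!paste(key, read_id) %in% dirty, key])
  jx[, reason := NA_character_]
  jx[!motif %in% canon, reason := "non_canonical"]
  jx[is.na(reason) & !key %in% clean_keys, reason := "no_clean_read"]
  jx[, hc := is.na(reason)]
  jx[]
}

#' Train a splice-site position weight matrix
#'
#' Builds donor (3 exonic + 10 intronic positions) and acceptor (14 intronic
#' + 3 exonic positions) matrices from the training junctions, with a
#' pseudocount of 1 per base and per-position log-odds. Raw scores are
#' affinely rescaled so the best achievable sequence scores 100 and the
#' worst 0. The default uniform background makes the matrix a pure
#' frequency model, so the training consensus is always the top-scoring
#' sequence; `background = "training"` uses the training set's overall
#' base composition instead.
#'
#' @param junctions data.frame with chrom, strand, intron_start, intron_end
#'   (e.g. the `hc == TRUE` rows of [call_high_confidence()]).
#' @param genome a `DNAStringSet`.
#' @param params a [pipeline_params()].
#' @param background `"uniform"` (default) or `"training"`.
#' @return an object of class `splice_site_pwm`.
#' @export
train_pwm <- function(junctions, genome, params = pipeline_params(),
                      background = c("uniform", "training")) {
  background <- match.arg(background)
  jx <- data.table::as.data.table(junctions)
  if (nrow(jx) == 0L) stopf("empty PWM training set")
  w <- pwm_windows(jx, genome, drop_oob = TRUE)
  if (length(w$donor) == 0L) stopf("no training junction with in-bounds windows")
  keep <- !grepl("N", w$donor) & !grepl("N", w$acceptor)
  if (!any(keep)) stopf("no training window free of N")
  donor <- w$donor[keep]; acceptor <- w$acceptor[keep]
  bg <- if (background == "uniform") {
    stats::setNames(rep(0.25, 4L), c("A", "C", "G", "T"))
  } else {
    bg_counts <- colSums(Biostrings::letterFrequency(
      Biostrings::DNAStringSet(c(donor, acceptor)), c("A", "C", "G", "T")))
    (bg_counts + 1) / (sum(bg_counts) + 4)
  }
  mat <- function(seqs) {
    m <- Biostrings::consensusMatrix(Biostrings::DNAStringSet(seqs),
                                     baseOnly = TRUE)[c("A", "C", "G", "T"), ,
                                                      drop = FALSE]
    freq <- (m + 1) / (length(seqs) + 4)
    log2(freq / bg)
  }
  dmat <- mat(donor); amat <- mat(acceptor)
  structure(list(
    donor = dmat, acceptor = amat, background = bg,
    donor_exonic = 3L, donor_intronic = 10L,
    acceptor_intronic = 14L, acceptor_exonic = 3L,
    donor_min = sum(apply(dmat, 2, min)), donor_max = sum(apply(dmat, 2, max)),
    acceptor_min = sum(apply(amat, 2, min)),
    acceptor_max = sum(apply(amat, 2, max)),
    n_training = length(donor)), class = "splice_site_pwm")
}

#' @export
print.splice_site_pwm <- function(x, ...) {
  cat(sprintf(paste0("splice-site PWM trained on %d junctions ",
                     "(donor %d+%d nt, acceptor %d+%d nt)\n"),
              x$n_training, x$donor_exonic, x$donor_intronic,
              x$acceptor_intronic, x$acceptor_exonic))
  invisible(x)
}

# donor/acceptor window sequences in transcription order
pwm_windows <- function(jx, genome, drop_oob = FALSE,
                        d_ex = 3L, d_in = 10L, a_in = 14L, a_ex = 3L) {
  lens <- genome_lengths(genome)[jx$chrom]
  plus <- jx$strand == "+"
  d_s <- ifelse(plus, jx$intron_start - d_ex, jx$intron_end - d_in)
  d_e <- ifelse(plus, jx$intron_start + d_in, jx$intron_end + d_ex)
  a_s <- ifelse(plus, jx$intron_end - a_in, jx$intron_start - a_ex)
  a_e <- ifelse(plus, jx$intron_end + a_ex, jx$intron_start + a_in)
  oob <- d_s < 0L | a_s < 0L | d_e > lens | a_e > lens
  if (any(oob) && !drop_oob) stopf("splice-site window off chromosome edge")
  ok <- which(!oob)
  if (!length(ok)) return(list(donor = character(), acceptor = character(),
                               index = integer()))
  donor <- genome_fetch(genome, jx$chrom[ok], d_s[ok], d_e[ok])
  acceptor <- genome_fetch(genome, jx$chrom[ok], a_s[ok], a_e[ok])
  minus <- !plus[ok]
  donor[minus] <- revcomp(donor[minus])
  acceptor[minus] <- revcomp(acceptor[minus])
  list(donor = donor, acceptor = acceptor, index = ok)
}

#' Score splice sites against a trained PWM
#'
#' Returns per-junction scaled donor (5') and acceptor (3') scores in
#' 0..100 and a `good` flag set when both reach `params$pwm_threshold`.
#' Positions reading N score that position's minimum log-odds.
#'
#' @param junctions data.frame with chrom, strand, intron_start, intron_end.
#' @param pwm a `splice_site_pwm` from [train_pwm()].
#' @param genome a `DNAStringSet`.
#' @param params a [pipeline_params()].
#' @return data.table of the input rows plus score5, score3, good.
#' @export
score_junctions <- function(junctions, pwm, genome, params = pipeline_params()) {
  jx <- data.table::as.data.table(junctions)
  w <- pwm_windows(jx, genome)
  score_seq <- function(seqs, mat) {
    pos_min <- apply(mat, 2, min)
    chars <- do.call(rbind, strsplit(seqs, ""))
    raw <- numeric(length(seqs))
    for (p in seq_len(ncol(mat))) {
      b <- chars[, p]
      v <- mat[, p][b]
      v[is.na(v)] <- pos_min[p]
      raw <- raw + v
    }
    raw
  }
  raw5 <- score_seq(w$donor, pwm$donor)
  raw3 <- score_seq(w$acceptor, pwm$acceptor)
  scale01 <- function(raw, lo, hi) {
    if (hi - lo <= 0) return(rep(100, length(raw)))
    pmin(pmax(100 * (raw - lo) / (hi - lo), 0), 100)
  }
  jx[, score5 := scale01(raw5, pwm$donor_min, pwm$donor_max)]
  jx[, score3 := scale01(raw3, pwm$acceptor_min, pwm$acceptor_max)]
  jx[, good := score5 >= params$pwm_threshold & score3 >= params$pwm_threshold]
  jx[]
}
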