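#' Simulation configuration
#'
#' Defines a synthetic study: a random genome with non-overlapping gene
#' models whose junctions carry canonical (or configurably non-canonical)
#' motifs, per-gene true TSS/TES sets with usage weights, embedded internal
#' A-runs, and a read model with the corruption modes the curation pipeline
#' is designed to defeat: per-base substitution/indel errors, junction
#' wander with compensating near-junction mismatches, 5'/3' degradation
#' and off-priming at templated A-runs. The seed fully determines every
#' output.
#'
#' @param n_chrom,chrom_length genome shape (default 2 x 250 kb).
#' @param n_genes number of genes (default 200).
#' @param p_mono_exon fraction of single-exon genes (default 0.15).
#' @param max_exons multi-exon genes draw 2..max_exons exons (default 8).
#' @param exon_len_range,intron_len_range internal exon and intron length
#'   ranges (defaults 80-300 and 60-200 nt).
#' @param terminal_exon_range first/last exon length range (250-400 nt),
#'   large enough to host alternative ends and degraded starts.
#' @param p_alt_tss,p_alt_tes probability of a second TSS/TES (default 0.3
#'   each), placed `alt_offset` nt internal to the primary site.
#' @param alt_offset distance between alternative and primary ends
#'   (default 120 nt, beyond the 100-nt window used downstream).
#' @param alt_weight usage weight of the alternative site (default 0.3).
#' @param end_jitter_sd per-read end dispersion around the chosen true site
#'   in nt (default 1; discretised normal clamped at 3).
#' @param p_arun fraction of genes with an internal templated A-run
#'   (default 0.4) of `arun_len` adenosines (default 8).
#' @param frac_gc_ag,frac_at_ac,frac_noncanonical fractions of introns
#'   carrying GC-AG / AT-AC / decoy non-canonical (CT-AC) motifs
#'   (defaults 0.05, 0.02, 0).
#' @param p_low_coverage fraction of genes with few reads (default 0.3,
#'   uniform 1..6 reads); the rest draw log-uniform
#'   `high_reads_range` (default 7-2000) reads.
#' @param sub_rate,ins_rate,del_rate per-base error rates
#'   (defaults 0.01, 0.00125, 0.00125).
#' @param junction_wander_prob per-read probability of one misplaced
#'   junction with compensating mismatches (default 0.05);
#'   `wander_max_shift` bounds the shift (default 4 nt).
#' @param p_degrade_5p,p_degrade_3p truncation probabilities (defaults 0.3,
#'   0.1); truncation length is `degrade_min` (60) plus an exponential of
#'   mean `degrade_mean` (240) nt.
#' @param p_offprime probability that a read of an A-run gene 3'-ends at
#'   the run instead of the poly(A) tail (default 0.5).
#' @param cap_fraction fraction of reads from the cap-enriched library
#'   (default 0.8).
#' @param rng_seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2L, chrom_length = 250000L, n_genes = 200L,
                       p_mono_exon = 0.15, max_exons = 8L,
                       exon_len_range = c(80L, 300L),
                       intron_len_range = c(60L, 200L),
                       terminal_exon_range = c(250L, 400L),
                       p_alt_tss = 0.3, p_alt_tes = 0.3, alt_offset = 120L,
                       alt_weight = 0.3, end_jitter_sd = 1,
                       p_arun = 0.4, arun_len = 8L,
                       frac_gc_ag = 0.05, frac_at_ac = 0.02,
                       frac_noncanonical = 0,
                       p_low_coverage = 0.3, high_reads_range = c(7L, 2000L),
                       sub_rate = 0.01, ins_rate = 0.00125, del_rate = 0.00125,
                       junction_wander_prob = 0.05, wander_max_shift = 4L,
                       p_degrade_5p = 0.3, p_degrade_3p = 0.1,
                       degrade_min = 60L, degrade_mean = 240,
                       p_offprime = 0.5, cap_fraction = 0.8,
                       rng_seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("p_mono_exon", "p_alt_tss", "p_alt_tes", "p_arun", "frac_gc_ag",
             "frac_at_ac", "frac_noncanonical", "p_low_coverage", "sub_rate",
             "ins_rate", "del_rate", "junction_wander_prob", "p_degrade_5p",
             "p_degrade_3p", "p_offprime", "cap_fraction")
  for (p in probs)
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must be in [0,1]", p)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with gene models
#'
#' Places non-overlapping genes on random sequence, embedding splice-site
#' motifs at every intron boundary (GT-AG by default, with configurable
#' GC-AG/AT-AC fractions and a non-canonical decoy fraction) and internal
#' A-runs where configured. Returns the genome, one transcript model per
#' TSS/TES combination of each gene, and the truth tables.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (DNAStringSet), `genes` (a
#'   [transcript_set()], one model per true isoform), and `truth` (list of
#'   data.tables: genes, junctions, ends).
#' @export
simulate_genome_and_genes <- function(config) {
  set.seed(config$rng_seed)
  glen <- config$chrom_length
  chroms <- sprintf("chr%d", seq_len(config$n_chrom))
  genome_chars <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), glen, replace = TRUE))
  names(genome_chars) <- chroms

  runif_int <- function(n, r) as.integer(floor(stats::runif(n, r[1L], r[2L] + 1)))
  genes <- vector("list", config$n_genes)
  jxs <- list(); ends <- list()
  cursor <- stats::setNames(rep(600L, config$n_chrom), chroms)
  ci <- 1L
  for (gi in seq_len(config$n_genes)) {
    ch <- chroms[ci]; ci <- ci %% config$n_chrom + 1L
    strand <- sample(c("+", "-"), 1L)
    mono <- stats::runif(1) < config$p_mono_exon
    k <- if (mono) 1L else sample(2:config$max_exons, 1L)
    alt_tss <- stats::runif(1) < config$p_alt_tss
    alt_tes <- stats::runif(1) < config$p_alt_tes
    el <- runif_int(k, config$exon_len_range)
    el[1L] <- runif_int(1L, config$terminal_exon_range)
    el[k] <- if (k > 1L) runif_int(1L, config$terminal_exon_range) else el[1L]
    if (mono) el[1L] <- el[1L] + 600L  # room for alt ends + degradation
    il <- if (k > 1L) runif_int(k - 1L, config$intron_len_range) else integer()
    body_len <- sum(el) + sum(il)
    gstart <- cursor[ch]
    if (gstart + body_len + 600L > glen)
      stopf("genes do not fit the chromosome; increase chrom_length")
    cursor[ch] <- gstart + body_len + runif_int(1L, c(300L, 800L))
    # genome-order exon blocks
    bs <- integer(k); be <- integer(k); p <- gstart
    for (i in seq_len(k)) {
      bs[i] <- p; be[i] <- p + el[i]
      p <- be[i] + if (i < k) il[i] else 0L
    }
    gid <- sprintf("SIM%04d", gi)
    # intron motifs on the transcribed strand
    if (k > 1L) {
      u <- stats::runif(k - 1L)
      cls <- ifelse(u < config$frac_noncanonical, "CT-AC",
             ifelse(u < config$frac_noncanonical + config$frac_gc_ag, "GC-AG",
             ifelse(u < config$frac_noncanonical + config$frac_gc_ag +
                      config$frac_at_ac, "AT-AC", "GT-AG")))
      for (i in seq_len(k - 1L)) {
        is0 <- be[i]; ie0 <- bs[i + 1L]
        dd <- substr(cls[i], 1L, 2L); aa <- substr(cls[i], 4L, 5L)
        if (strand == "+") {
          genome_chars[[ch]][(is0 + 1L):(is0 + 2L)] <- strsplit(dd, "")[[1L]]
          genome_chars[[ch]][(ie0 - 1L):ie0] <- strsplit(aa, "")[[1L]]
        } else {
          # transcription right-to-left: donor at the right edge
          genome_chars[[ch]][(ie0 - 1L):ie0] <-
            rev(strsplit(chartr("ACGT", "TGCA", dd), "")[[1L]])
          genome_chars[[ch]][(is0 + 1L):(is0 + 2L)] <-
            rev(strsplit(chartr("ACGT", "TGCA", aa), "")[[1L]])
        }
        # transcription-order junction key
        jxs[[length(jxs) + 1L]] <- data.table::data.table(
          gene_id = gid, chrom = ch, strand = strand,
          intron_start = is0, intron_end = ie0, motif_class = cls[i])
      }
    }
    tx_len <- sum(el)
    # transcription-order ends (genomic positions)
    if (strand == "+") {
      tss <- c(gstart, if (alt_tss) tx_pos_to_genome_scalar(
        config$alt_offset, bs, be, strand))
      tes <- c(be[k] - 1L, if (alt_tes) tx_pos_to_genome_scalar(
        tx_len - 1L - config$alt_offset, bs, be, strand))
    } else {
      tss <- c(be[k] - 1L, if (alt_tss) tx_pos_to_genome_scalar(
        config$alt_offset, bs, be, strand))
      tes <- c(gstart, if (alt_tes) tx_pos_to_genome_scalar(
        tx_len - 1L - config$alt_offset, bs, be, strand))
    }
    # a true TES immediately followed by genomic poly(A) is by definition
    # indistinguishable from off-priming, so the generator never creates
    # such ambiguous sites: cap templated A in the downstream window
    for (tp in tes) {
      win <- if (strand == "+") (tp + 1L):(tp + 10L) else (tp - 10L):(tp - 1L)
      base <- if (strand == "+") "A" else "T"
      hitA <- win[genome_chars[[ch]][win + 1L] == base]
      if (length(hitA) > 5L)
        genome_chars[[ch]][hitA[-seq_len(5L)] + 1L] <- "C"
    }
    # internal A-run, fully inside one exon, mid-transcript
    arun_tx <- NA_integer_
    if (stats::runif(1) < config$p_arun) {
      target <- as.integer(floor(tx_len * 0.6))
      # exon bounds in transcript space follow transcription order
      cum <- cumsum(c(0L, if (strand == "-") rev(el) else el))
      ei <- findInterval(target, cum, rightmost.closed = FALSE)
      lo <- cum[ei]; hi <- cum[ei + 1L] - 1L
      # the base before the run (the off-primed end) and the downstream
      # 10-nt priming window must all sit in this exon, genome-contiguous
      start_tx <- min(max(target, lo + 1L), hi - 9L)
      if (start_tx > max(config$degrade_min, config$alt_offset) + 100L &&
          start_tx > lo && start_tx + 9L <= hi &&
          start_tx + config$arun_len - 1L < tx_len - 150L) {
        arun_tx <- start_tx
        gpos <- vapply(start_tx:(start_tx + config$arun_len - 1L),
                       tx_pos_to_genome_scalar, numeric(1L),
                       bs = bs, be = be, strand = strand)
        base <- if (strand == "+") "A" else "T"
        genome_chars[[ch]][as.integer(gpos) + 1L] <- base
      }
    }
    genes[[gi]] <- list(gene_id = gid, chrom = ch, strand = strand,
                        bs = bs, be = be, el = el, tx_len = tx_len,
                        tss = tss, tes = tes, arun_tx = arun_tx)
    wts <- function(v) if (length(v) == 2L) c(1 - config$alt_weight,
                                              config$alt_weight) else 1
    ends[[length(ends) + 1L]] <- data.table::rbindlist(list(
      data.table::data.table(gene_id = gid, side = "start5", chrom = ch,
                             strand = strand, pos = as.integer(tss),
                             weight = wts(tss),
                             dominant = seq_along(tss) == 1L),
      data.table::data.table(gene_id = gid, side = "end3", chrom = ch,
                             strand = strand, pos = as.integer(tes),
                             weight = wts(tes),
                             dominant = seq_along(tes) == 1L)))
  }
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste, character(1L),
                                            collapse = ""))
  names(genome) <- chroms
  truth_junc <- if (length(jxs)) data.table::rbindlist(jxs) else
    data.table::data.table(gene_id = character(), chrom = character(),
                           strand = character(), intron_start = integer(),
                           intron_end = integer(), motif_class = character())
  truth_junc[, key := junction_key(chrom, strand, intron_start, intron_end)]
  gene_dt <- data.table::rbindlist(lapply(genes, function(g)
    data.table::data.table(gene_id = g$gene_id, chrom = g$chrom,
                           strand = g$strand, start = g$bs[1L],
                           end = g$be[length(g$be)], n_exons = length(g$bs),
                           tx_len = g$tx_len, arun_tx = g$arun_tx)))
  # one transcript model per TSS/TES combination
  models <- list(); mblocks <- list()
  for (g in genes) {
    combo <- expand.grid(tss = g$tss, tes = g$tes)
    for (i in seq_len(nrow(combo))) {
      tid <- sprintf("%s.%d", g$gene_id, i)
      s_tx <- genome_pos_to_tx_scalar(combo$tss[i], g$bs, g$be, g$strand)
      e_tx <- genome_pos_to_tx_scalar(combo$tes[i], g$bs, g$be, g$strand)
      b <- tx_span_to_blocks(s_tx, e_tx, g$bs, g$be, g$strand)
      models[[tid]] <- data.table::data.table(
        transcript_id = tid, gene_id = g$gene_id, chrom = g$chrom,
        strand = g$strand, source = "other", support = 1L)
      mblocks[[tid]] <- data.table::data.table(
        transcript_id = tid, start = b$start, end = b$end)
    }
  }
  gene_models <- if (length(models)) {
    transcript_set(data.table::rbindlist(models),
                   data.table::rbindlist(mblocks))
  } else {
    transcript_set(
      data.table::data.table(transcript_id = character(), chrom = character(),
                             strand = character()),
      data.table::data.table(transcript_id = character(), start = integer(),
                             end = integer()))
  }
  list(genome = genome, genes = gene_models, gene_defs = genes,
       truth = list(genes = gene_dt, junctions = truth_junc,
                    ends = data.table::rbindlist(ends)))
}

# gene-local coordinate helpers; bs/be are genome-order exon bounds
tx_pos_to_genome_scalar <- function(t, bs, be, strand) {
  el <- be - bs
  if (strand == "-") { bs <- rev(bs); be <- rev(be); el <- rev(el) }
  cum <- cumsum(c(0L, el))
  i <- findInterval(t, cum, rightmost.closed = FALSE)
  off <- t - cum[i]
  if (strand == "+") bs[i] + off else be[i] - 1L - off
}

genome_pos_to_tx_scalar <- function(g, bs, be, strand) {
  el <- be - bs
  if (strand == "+") {
    i <- findInterval(g, bs)
    sum(el[seq_len(i - 1L)]) + (g - bs[i])
  } else {
    rbs <- rev(bs); rbe <- rev(be); rel <- rev(el)
    i <- which(g >= rbs & g < rbe)
    sum(rel[seq_len(i - 1L)]) + (rbe[i] - 1L - g)
  }
}

# genome blocks (sorted) covering transcription-order tx span [s, e]
tx_span_to_blocks <- function(s, e, bs, be, strand) {
  el <- be - bs
  obs <- bs; obe <- be; oel <- el
  if (strand == "-") { obs <- rev(bs); obe <- rev(be); oel <- rev(el) }
  cum <- cumsum(c(0L, oel))
  i1 <- findInterval(s, cum, rightmost.closed = FALSE)
  i2 <- findInterval(e, cum, rightmost.closed = FALSE)
  out_s <- integer(); out_e <- integer()
  for (i in i1:i2) {
    lo <- max(s, cum[i]); hi <- min(e, cum[i + 1L] - 1L)
    if (strand == "+") {
      out_s <- c(out_s, obs[i] + (lo - cum[i]))
      out_e <- c(out_e, obs[i] + (hi - cum[i]) + 1L)
    } else {
      out_s <- c(out_s, obe[i] - 1L - (hi - cum[i]))
      out_e <- c(out_e, obe[i] - (lo - cum[i]))
    }
  }
  o <- order(out_s)
  list(start = out_s[o], end = out_e[o])
}

#' Simulate long reads at alignment level
#'
#' Draws reads per gene, chooses true TSS/TES by usage weight with small
#' jitter, applies 5'/3' degradation, off-priming at A-runs, junction
#' wander with compensating near-junction substitutions, and per-base
#' errors, and emits alignment-level records directly (no mapper needed).
#'
#' @param config a [sim_config()].
#' @param sim output of [simulate_genome_and_genes()] for the same config.
#' @return list with `reads` (a [read_set()]) and `truth_reads` (per-read
#'   label table); `sim$truth$ends` gains an `n_support` column counting
#'   eligible emitted reads within the sliding window of each true end.
#' @export
simulate_reads <- function(config, sim) {
  set.seed(config$rng_seed + 1L)
  defs <- sim$gene_defs
  ng <- length(defs)
  low <- stats::runif(ng) < config$p_low_coverage
  hr <- config$high_reads_range
  nreads <- ifelse(low,
                   1L + as.integer(floor(stats::runif(ng) * 6)),
                   as.integer(round(exp(stats::runif(ng, log(hr[1L]),
                                                     log(hr[2L]))))))
  reads_l <- list(); blocks_l <- list(); mism_l <- list(); truth_l <- list()
  serial <- 0L
  for (g_i in seq_len(ng)) {
    g <- defs[[g_i]]
    n <- nreads[g_i]
    ids <- sprintf("R%07d", serial + seq_len(n)); serial <- serial + n
    # choose ends (tx coordinates)
    pick <- function(sites) {
      w <- if (length(sites) == 2L) c(1 - config$alt_weight, config$alt_weight)
        else 1
      sites[sample.int(length(sites), n, replace = TRUE, prob = w)]
    }
    tss_g <- pick(g$tss); tes_g <- pick(g$tes)
    s_tx <- vapply(tss_g, genome_pos_to_tx_scalar, numeric(1L),
                   bs = g$bs, be = g$be, strand = g$strand)
    e_tx <- vapply(tes_g, genome_pos_to_tx_scalar, numeric(1L),
                   bs = g$bs, be = g$be, strand = g$strand)
    jit <- function(m) pmax(pmin(round(stats::rnorm(m, 0, config$end_jitter_sd)),
                                 3L), -3L)
    s_tx <- pmax(s_tx + jit(n), 0)
    e_tx <- pmin(e_tx + jit(n), g$tx_len - 1L)
    # off-priming replaces the 3' end; 3' degradation otherwise
    off <- !is.na(g$arun_tx) & stats::runif(n) < config$p_offprime
    e_tx[off] <- g$arun_tx - 1L
    deg3 <- !off & stats::runif(n) < config$p_degrade_3p
    trunc3 <- config$degrade_min +
      as.integer(floor(stats::rexp(n, 1 / config$degrade_mean)))
    e_tx[deg3] <- e_tx[deg3] - trunc3[deg3]
    deg5 <- stats::runif(n) < config$p_degrade_5p
    trunc5 <- config$degrade_min +
      as.integer(floor(stats::rexp(n, 1 / config$degrade_mean)))
    s_tx[deg5] <- s_tx[deg5] + trunc5[deg5]
    # keep reads viable: cancel truncations that leave < 50 nt
    bad5 <- deg5 & (e_tx - s_tx < 50L)
    s_tx[bad5] <- pmax(vapply(tss_g[bad5], genome_pos_to_tx_scalar, numeric(1L),
                              bs = g$bs, be = g$be, strand = g$strand), 0)
    deg5[bad5] <- FALSE
    bad3 <- deg3 & (e_tx - s_tx < 50L)
    e_tx[bad3] <- pmin(vapply(tes_g[bad3], genome_pos_to_tx_scalar, numeric(1L),
                              bs = g$bs, be = g$be, strand = g$strand),
                       g$tx_len - 1L)
    deg3[bad3] <- FALSE
    cap <- stats::runif(n) < config$cap_fraction
    # blocks
    wander <- stats::runif(n) < config$junction_wander_prob
    wkey_true <- rep(NA_character_, n); wkey_shift <- rep(NA_character_, n)
    for (r in seq_len(n)) {
      b <- tx_span_to_blocks(s_tx[r], e_tx[r], g$bs, g$be, g$strand)
      mm_extra <- NULL
      nb <- length(b$start)
      blen <- b$end - b$start
      # wander needs room on both flanking exons for the shift plus the
      # compensating mismatches (terminal blocks may be truncated)
      roomy <- if (nb > 1L) which(blen[-nb] >= config$wander_max_shift + 3L &
                                    blen[-1L] >= config$wander_max_shift + 3L)
               else integer()
      if (wander[r] && length(roomy)) {
        j <- roomy[sample.int(length(roomy), 1L)]  # intron after block j
        delta <- sample(c(-(1:config$wander_max_shift),
                          1:config$wander_max_shift), 1L)
        donor_side <- stats::runif(1) < 0.5
        is0 <- b$end[j]; ie0 <- b$start[j + 1L]
        wkey_true[r] <- junction_key(g$chrom, g$strand, is0, ie0)
        if (donor_side) {
          b$end[j] <- is0 + delta
          edge <- b$end[j]
          mm_pos <- c(edge - 1L, edge - 2L)
        } else {
          b$start[j + 1L] <- ie0 + delta
          edge <- b$start[j + 1L]
          mm_pos <- c(edge, edge + 1L)
        }
        wkey_shift[r] <- junction_key(g$chrom, g$strand, b$end[j],
                                      b$start[j + 1L])
        mm_extra <- data.table::data.table(read_id = ids[r], pos = mm_pos,
                                           kind = "sub", len = 1L)
      } else {
        wander[r] <- FALSE
      }
      blocks_l[[length(blocks_l) + 1L]] <- data.table::data.table(
        read_id = ids[r], start = b$start, end = b$end)
      if (!is.null(mm_extra)) mism_l[[length(mism_l) + 1L]] <- mm_extra
    }
    # per-base errors over the aligned tx footprint
    alen <- as.integer(e_tx - s_tx + 1L)
    nerr <- stats::rbinom(n, alen,
                          config$sub_rate + config$ins_rate + config$del_rate)
    tot_rate <- config$sub_rate + config$ins_rate + config$del_rate
    has <- which(nerr > 0L)
    if (length(has) && tot_rate > 0) {
      tx_off <- unlist(lapply(has, function(r)
        sample.int(alen[r], nerr[r])) , use.names = FALSE) - 1L
      rid <- rep(ids[has], nerr[has])
      sr <- rep(s_tx[has], nerr[has])
      gpos <- vapply(seq_along(tx_off), function(i)
        tx_pos_to_genome_scalar(sr[i] + tx_off[i], g$bs, g$be, g$strand),
        numeric(1L))
      kind <- sample(c("sub", "ins", "del"), length(tx_off), replace = TRUE,
                     prob = c(config$sub_rate, config$ins_rate,
                              config$del_rate) / tot_rate)
      mism_l[[length(mism_l) + 1L]] <- unique(data.table::data.table(
        read_id = rid, pos = as.integer(gpos), kind = kind, len = 1L))
    }
    reads_l[[g_i]] <- data.table::data.table(
      read_id = ids, library_id = ifelse(cap, "teloprime", "clontech"),
      chrom = g$chrom, strand = g$strand, cap = cap)
    truth_l[[g_i]] <- data.table::data.table(
      read_id = ids, gene_id = g$gene_id, tss_true = as.integer(tss_g),
      tes_true = as.integer(tes_g), degraded5 = deg5, degraded3 = deg3,
      offprimed = off, wandered = wander, wander_key_true = wkey_true,
      wander_key_shifted = wkey_shift, n_errors = nerr)
  }
  mism <- if (length(mism_l)) unique(data.table::rbindlist(mism_l)) else NULL
  rs <- read_set(data.table::rbindlist(reads_l),
                 data.table::rbindlist(blocks_l), mism)
  truth_reads <- data.table::rbindlist(truth_l)
  sim$truth$ends <- end_support_counts(sim$truth$ends, rs, truth_reads)
  sim$truth$junctions <- junction_clean_support(sim$truth$junctions, rs)
  list(reads = rs, truth_reads = truth_reads, truth = sim$truth)
}

# count, per true end, the eligible emitted reads whose corresponding read
# end lies within the supported-call sliding window (+-5 nt)
end_support_counts <- function(truth_ends, rs, truth_reads, halfwidth = 5L) {
  reads <- rs$reads
  out <- data.table::copy(truth_ends)
  start_pos <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  end_pos <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  gmap <- merge(data.table::data.table(read_id = reads$read_id,
                                       cap = reads$cap,
                                       sp = start_pos, ep = end_pos),
                truth_reads[, c("read_id", "gene_id")], by = "read_id")
  out[, n_support := {
    gr <- gmap[gene_id == .BY$gene_id]
    if (.BY$side == "start5") {
      vapply(pos, function(p) sum(gr$cap & abs(gr$sp - p) <= halfwidth),
             integer(1L))
    } else {
      vapply(pos, function(p) sum(abs(gr$ep - p) <= halfwidth), integer(1L))
    }
  }, by = c("gene_id", "side")]
  out
}

# flag true junctions supported by >= 1 emitted read carrying the junction
# with no mismatch event within `near` nt on either exonic side; computed
# by direct interval arithmetic on the emitted records
junction_clean_support <- function(truth_junc, rs, near = 10L) {
  bl <- rs$blocks
  ji <- bl[, if (.N > 1L) list(up_start = start[-.N], is0 = end[-.N],
                               ie0 = start[-1L], down_end = end[-1L]),
           by = read_id]
  out <- data.table::copy(truth_junc)
  if (nrow(ji) == 0L) { out[, clean_support := FALSE]; return(out) }
  ji <- merge(ji, rs$reads[, c("read_id", "chrom", "strand")], by = "read_id")
  ji[, key := junction_key(chrom, strand, is0, ie0)]
  mm <- rs$mismatches
  dirty <- character()
  if (nrow(mm)) {
    mm2 <- data.table::copy(mm)
    mm2[, fs := ifelse(kind == "ins", pos - 1L, pos)]
    mm2[, fe := ifelse(kind == "del", pos + len - 1L, pos)]
    win <- data.table::rbindlist(list(
      ji[, list(read_id, key, lo = pmax(up_start, is0 - near), hi = is0 - 1L)],
      ji[, list(read_id, key, lo = ie0, hi = pmin(down_end, ie0 + near) - 1L)]))
    win <- win[hi >= lo]
    data.table::setkey(win, read_id, lo, hi)
    hit <- data.table::foverlaps(mm2, win, by.x = c("read_id", "fs", "fe"),
                                 nomatch = NULL)
    dirty <- unique(hit[, paste(key, read_id)])
  }
  clean_keys <- unique(ji[!paste(key, read_id) %in% dirty, key])
  out[, clean_support := key %in% clean_keys]
  out
}

#' Precision/recall of calls against simulation truth
#'
#' Splice junctions are matched exactly by key; end calls within
#' `tolerance` nt. For junctions the recall denominator is the true
#' junctions with at least one clean supporting read (column
#' `clean_support`); for ends it is the dominant true site of each
#' gene/side with at least `min_support` concordant reads (column
#' `n_support`), the sites the stratified caller is designed to recover.
#' Precision counts calls matching any true junction/site.
#'
#' @param calls character vector of junction keys (`type = "sj"`) or a
#'   data.table with chrom, strand, side, pos (`type = "ends"`).
#' @param truth the `truth` list of [simulate_reads()].
#' @param type `"sj"` or `"ends"`.
#' @param tolerance match window for ends (default 50 nt).
#' @param min_support concordant-read threshold for the end denominator
#'   (default 2).
#' @return one-row data.table with tp, fp, fn, precision, recall.
#' @export
truth_eval <- function(calls, truth, type = c("sj", "ends"), tolerance = 50L,
                       min_support = 2L) {
  type <- match.arg(type)
  if (type == "sj") {
    tkeys <- truth$junctions[
      if ("clean_support" %in% names(truth$junctions)) clean_support else TRUE,
      key]
    tp <- sum(calls %in% truth$junctions$key)
    fp <- sum(!calls %in% truth$junctions$key)
    fn <- sum(!tkeys %in% calls)
    tp_rec <- sum(tkeys %in% calls)
    data.table::data.table(
      type = "sj", tp = tp, fp = fp, fn = fn,
      precision = if (length(calls)) tp / length(calls) else NA_real_,
      recall = if (length(tkeys)) tp_rec / length(tkeys) else NA_real_)
  } else {
    te <- truth$ends
    denom <- te[dominant == TRUE &
                  (if ("n_support" %in% names(te)) n_support >= min_support
                   else TRUE)]
    calls <- data.table::as.data.table(calls)
    match_any <- function(q, t) {
      if (nrow(q) == 0L) return(logical(0L))
      vapply(seq_len(nrow(q)), function(i) {
        cand <- t[chrom == q$chrom[i] & strand == q$strand[i] &
                    side == q$side[i]]
        any(abs(cand$pos - q$pos[i]) <= tolerance)
      }, logical(1L))
    }
    hit_call <- match_any(calls, te)
    hit_truth <- match_any(denom, calls)
    tp <- sum(hit_truth); fn <- sum(!hit_truth)
    fp <- sum(!hit_call)
    data.table::data.table(
      type = "ends", tp = tp, fp = fp, fn = fn,
      precision = if (nrow(calls)) sum(hit_call) / nrow(calls) else NA_real_,
      recall = if (nrow(denom)) tp / nrow(denom) else NA_real_)
  }
}
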