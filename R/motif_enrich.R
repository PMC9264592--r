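#' Motif specifications
#'
#' Motifs are IUPAC degenerate patterns scanned on the oriented flank
#' around a site. `default_motifs()` provides a standard set of promoter
#' and polyadenylation elements (TATA box, initiator, Y-patch, Kozak
#' context, poly(A) signal, CFIm element); any set can be supplied as a
#' TSV with columns `name`, `pattern` and optional `note`.
#'
#' @return data.table with columns name, pattern, note.
#' @export
default_motifs <- function() {
  data.table::data.table(
    name = c("TATA", "Inr", "Ypatch", "Kozak", "PAS", "CFIm"),
    pattern = c("TATAWAW", "YYANWYY", "YYYYYYYY", "RNNATGG", "AATAAA", "TGTA"),
    note = c("TATA box, ~25-35 nt upstream of TSS",
             "initiator, overlapping TSS",
             "pyrimidine patch upstream of TSS (plants)",
             "translation start context downstream of TSS",
             "polyadenylation signal upstream of TES",
             "cleavage factor Im element upstream of PAS"))
}

#' @rdname default_motifs
#' @param path TSV file with columns name, pattern (IUPAC), optional note.
#' @export
read_motifs <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!all(c("name", "pattern") %in% names(dt)))
    stopf("motif TSV needs columns name, pattern")
  if (!"note" %in% names(dt)) dt[, note := ""]
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(dt$pattern))
  if (any(bad)) stopf("non-IUPAC motif pattern: %s", dt$pattern[bad][1L])
  dt[, pattern := toupper(pattern)]
  dt[]
}

# IUPAC pattern -> regex character classes; N expands to [ACGT] so that
# N in the *subject* (edge padding) never matches
iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(map[strsplit(toupper(pattern), "")[[1L]]], collapse = "")
}

#' Extract oriented flanks around sites
#'
#' Extracts the `2*halfwidth + 1` nt window centred on each site. Minus
#' strand flanks are reverse-complemented so downstream is rightward and
#' the site base sits at index `halfwidth + 1`. Sites nearer than
#' `halfwidth` to a chromosome edge are padded with N and flagged.
#'
#' @param sites data.frame with columns chrom, strand, pos (0-based site).
#' @param genome a `DNAStringSet`.
#' @param halfwidth flank half-width in nt (default 500).
#' @return data.table with the site columns plus `seq` and `padded`.
#' @export
extract_flanks <- function(sites, genome, halfwidth = 500L) {
  st <- data.table::as.data.table(sites)
  if (!all(st$chrom %in% names(genome)))
    stopf("chromosome absent from genome: %s",
          paste(setdiff(unique(st$chrom), names(genome)), collapse = ", "))
  lens <- genome_lengths(genome)[st$chrom]
  s <- st$pos - halfwidth
  e <- st$pos + halfwidth + 1L
  cs <- pmax(s, 0L)
  ce <- pmin(e, lens)
  seqs <- genome_fetch(genome, st$chrom, cs, ce)
  padl <- cs - s
  padr <- e - ce
  seqs <- paste0(strrep("N", padl), seqs, strrep("N", padr))
  minus <- st$strand == "-"
  seqs[minus] <- revcomp(seqs[minus])
  st[, seq := seqs]
  st[, padded := (padl + padr) > 0L]
  st[]
}

#' Scan a motif over oriented flanks
#'
#' Records every match start at its position relative to the site (site =
#' 0, upstream negative). Overlapping matches are all counted by default;
#' N in the flank never matches.
#'
#' @param flanks output of [extract_flanks()].
#' @param motif one row of a motif table (name, pattern).
#' @param overlapping count overlapping matches (default TRUE).
#' @return an object of class `positional_counts`: data.table with columns
#'   motif, rel_pos, count; attributes `n_sites` and `total_matches`.
#' @export
scan_motifs <- function(flanks, motif, overlapping = TRUE) {
  stopifnot(nrow(flanks) >= 1L)
  hw <- (nchar(flanks$seq[1L]) - 1L) %/% 2L
  len <- nchar(motif$pattern)
  rx <- iupac_regex(motif$pattern)
  if (overlapping) rx <- paste0("(?=", rx, ")")
  m <- gregexpr(rx, flanks$seq, perl = TRUE)
  starts <- unlist(lapply(m, function(x) x[x > 0L]))
  rel <- starts - 1L - hw
  grid <- seq(-hw, hw - len + 1L)
  counts <- integer(length(grid))
  if (length(rel)) {
    tab <- table(rel)
    idx <- match(as.integer(names(tab)), grid)
    counts[idx] <- as.integer(tab)
  }
  out <- data.table::data.table(motif = motif$name, rel_pos = grid,
                                count = counts)
  data.table::setattr(out, "n_sites", nrow(flanks))
  data.table::setattr(out, "total_matches", sum(counts))
  data.table::setattr(out, "class", c("positional_counts", class(out)))
  out
}

#' Sample random control sites
#'
#' Uniform positions over the genome (chromosomes weighted by length, both
#' strands equiprobable), reproducible under the seed.
#'
#' @param genome a `DNAStringSet`.
#' @param n_sites number of sites (>= 1).
#' @param seed integer seed.
#' @return data.table with chrom, strand, pos.
#' @export
sample_random_control <- function(genome, n_sites, seed) {
  if (n_sites < 1L) stopf("n_sites must be >= 1")
  lens <- genome_lengths(genome)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  chrom <- sample(names(lens), n_sites, replace = TRUE, prob = lens / sum(lens))
  pos <- floor(stats::runif(n_sites) * lens[chrom])
  strand <- sample(c("+", "-"), n_sites, replace = TRUE)
  data.table::data.table(chrom = chrom, strand = strand, pos = as.integer(pos))
}

#' Two-proportion z-test
#'
#' Two-sample z-test on proportions with pooled variance and no continuity
#' correction; the p-value comes from the standard normal and is floored at
#' the smallest representable double. [format_pvalue()] renders values
#' below 2.2e-16 as "< 2.2e-16" as conventional in text output.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list with estimate1, estimate2, z, p_value.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 < 1L || n2 < 1L) stopf("both sample sizes must be >= 1")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stopf("counts out of range")
  p1 <- x1 / n1; p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  p <- max(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  list(estimate1 = p1, estimate2 = p2, z = z, p_value = p)
}

#' @rdname proportion_test
#' @param p a p-value.
#' @export
format_pvalue <- function(p) {
  if (p < 2.2e-16) "< 2.2e-16" else format(p, digits = 4)
}

#' Motif enrichment of a site set against a control
#'
#' Scans each motif over the flanks of the site set and of a random (or
#' supplied) control of equal size, counts sites with at least one match
#' (optionally restricted to a relative-position window), and compares the
#' two proportions with [proportion_test()].
#'
#' @param sites data.frame with chrom, strand, pos.
#' @param genome a `DNAStringSet`.
#' @param motifs motif table (default [default_motifs()]).
#' @param control optional control site set; defaults to
#'   [sample_random_control()] of the same size.
#' @param control_seed seed for the random control.
#' @param window optional c(lo, hi) relative-position window for counting.
#' @param halfwidth flank half-width (default 500).
#' @return list with `positional` (rbind of per-motif positional counts for
#'   sites and control) and `summary` (per-motif counts and p-values).
#' @export
motif_enrichment <- function(sites, genome, motifs = default_motifs(),
                             control = NULL, control_seed = 1L,
                             window = NULL, halfwidth = 500L) {
  if (is.null(control))
    control <- sample_random_control(genome, nrow(sites), control_seed)
  fl_s <- extract_flanks(sites, genome, halfwidth)
  fl_c <- extract_flanks(control, genome, halfwidth)
  pos_all <- list(); summ <- list()
  for (i in seq_len(nrow(motifs))) {
    mt <- motifs[i]
    ps <- scan_motifs(fl_s, mt); pc <- scan_motifs(fl_c, mt)
    ps[, set := "sites"]; pc[, set := "control"]
    pos_all[[i]] <- data.table::rbindlist(list(ps, pc))
    hits <- function(fl, counts) {
      sub <- if (is.null(window)) counts else
        counts[rel_pos >= window[1L] & rel_pos <= window[2L]]
      # sites with >= 1 match: rescan per site within window
      rx <- paste0("(?=", iupac_regex(mt$pattern), ")")
      seqs <- if (is.null(window)) fl$seq else
        substr(fl$seq, halfwidth + 1L + window[1L], halfwidth + 1L + window[2L] +
                 nchar(mt$pattern) - 1L)
      sum(vapply(gregexpr(rx, seqs, perl = TRUE),
                 function(x) any(x > 0L), logical(1L)))
    }
    x1 <- hits(fl_s, ps); x2 <- hits(fl_c, pc)
    pt <- proportion_test(x1, nrow(fl_s), x2, nrow(fl_c))
    summ[[i]] <- data.table::data.table(
      motif = mt$name, sites_with_motif = x1, control_with_motif = x2,
      n_sites = nrow(fl_s), z = pt$z, p_value = pt$p_value)
  }
  list(positional = data.table::rbindlist(pos_all),
       summary = data.table::rbindlist(summ))
}
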