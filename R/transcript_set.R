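#' Transcript models
#'
#' A `transcript_set` holds transcript models (exon blocks, strand, optional
#' CDS interval, source tag and read support) in the same 0-based half-open
#' forward-strand convention as [read_set()]. Models move through collapse,
#' filtering, rescue and merging unchanged in representation.
#'
#' @param transcripts data.frame with columns `transcript_id`, `chrom`,
#'   `strand`, and optionally `gene_id`, `cds_start`, `cds_end` (0-based
#'   half-open genomic CDS interval), `source` (one of isoseq/rtd2/
#'   araport/other) and `support` (reads merged in, >= 1).
#' @param blocks data.frame with columns `transcript_id`, `start`, `end`.
#' @param validate check block and CDS invariants (default TRUE).
#' @return an object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, blocks, validate = TRUE) {
  tr <- data.table::as.data.table(transcripts)
  bl <- data.table::as.data.table(blocks)
  if (!all(c("transcript_id", "chrom", "strand") %in% names(tr)))
    stopf("transcripts table needs transcript_id, chrom, strand")
  if (!all(c("transcript_id", "start", "end") %in% names(bl)))
    stopf("blocks table needs transcript_id, start, end")
  if (!"gene_id" %in% names(tr)) tr[, gene_id := NA_character_]
  if (!"cds_start" %in% names(tr)) tr[, cds_start := NA_integer_]
  if (!"cds_end" %in% names(tr)) tr[, cds_end := NA_integer_]
  if (!"source" %in% names(tr)) tr[, source := "other"]
  if (!"support" %in% names(tr)) tr[, support := 1L]
  bl[, `:=`(start = as.integer(start), end = as.integer(end))]
  tr[, `:=`(cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
            support = as.integer(support))]
  data.table::setkey(bl, transcript_id, start)
  span <- if (nrow(bl) == 0L) {
    data.table::data.table(transcript_id = character(), start = integer(),
                           end = integer(), n_blocks = integer())
  } else {
    bl[, list(start = min(start), end = max(end), n_blocks = .N),
       by = transcript_id]
  }
  tr <- merge(tr[, setdiff(names(tr), c("start", "end", "n_blocks")), with = FALSE],
              span, by = "transcript_id", sort = FALSE)
  if (validate) {
    if (anyDuplicated(tr$transcript_id)) stopf("duplicate transcript_id")
    if (any(bl$end <= bl$start)) stopf("empty or inverted exon block")
    gap <- bl[, list(bad = .N > 1L && any(start[-1L] - end[-.N] < 1L)),
              by = transcript_id]
    if (any(gap$bad)) stopf("overlapping or abutting exon blocks in transcript")
    if (any(tr$support < 1L)) stopf("support must be >= 1")
    has_cds <- !is.na(tr$cds_start)
    if (any(has_cds & (tr$cds_start < tr$start | tr$cds_end > tr$end)))
      stopf("CDS interval outside transcript span")
  }
  data.table::setorder(tr, chrom, start, transcript_id)
  structure(list(transcripts = tr, blocks = bl), class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  tr <- x$transcripts
  cat(sprintf("transcript_set: %d models on %d chromosome(s)\n",
              nrow(tr), length(unique(tr$chrom))))
  if (nrow(tr)) {
    src <- table(tr$source)
    cat("  sources:", paste(sprintf("%s=%d", names(src), src), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Subset or concatenate transcript sets
#'
#' `ts_subset` keeps the models named in `ids` (both tables in step);
#' `ts_bind` concatenates two sets.
#'
#' @param ts,a,b [transcript_set()] objects.
#' @param ids character vector of transcript ids to keep.
#' @return a [transcript_set()].
#' @export
ts_subset <- function(ts, ids) {
  keep <- ts$transcripts$transcript_id %in% ids
  transcript_set(ts$transcripts[keep],
                 ts$blocks[ts$blocks$transcript_id %in% ids],
                 validate = FALSE)
}

#' @rdname ts_subset
#' @export
ts_bind <- function(a, b) {
  transcript_set(
    data.table::rbindlist(list(a$transcripts, b$transcripts), fill = TRUE),
    data.table::rbindlist(list(a$blocks, b$blocks)),
    validate = FALSE)
}

#' Read transcript models from BED12 or GTF
#'
#' BED12 (0-based half-open) is read natively; GTF (1-based inclusive, exon
#' and optional CDS features grouped by `transcript_id`) is converted to the
#' internal convention at the boundary. CDS features are assembled into a
#' single genomic interval per transcript.
#'
#' @param path input file; format chosen by extension unless given.
#' @param format `"auto"`, `"bed"` or `"gtf"`.
#' @param source source tag stored on the models (default `"other"`; BED
#'   input has no source field of its own).
#' @return a [transcript_set()]. Transcripts rejected for overlapping blocks
#'   are reported in the `"rejected"` attribute.
#' @export
read_transcripts <- function(path, format = c("auto", "bed", "gtf"),
                             source = "other") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gtf", "gff")) "gtf" else "bed"
  }
  if (format == "bed") read_transcripts_bed(path, source)
  else read_transcripts_gtf(path, source)
}

read_transcripts_bed <- function(path, source) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) {
    return(transcript_set(
      data.table::data.table(transcript_id = character(), chrom = character(),
                             strand = character()),
      data.table::data.table(transcript_id = character(), start = integer(),
                             end = integer()),
      validate = FALSE))
  }
  ids <- gr$name
  if (is.null(ids) || anyNA(ids)) stopf("BED12 input needs transcript names")
  chrom0 <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  blocks <- gr$blocks
  nb <- S4Vectors::elementNROWS(blocks)
  ub <- unlist(blocks)
  bl <- data.table::data.table(
    transcript_id = rep(ids, nb),
    start = rep(start0, nb) + IRanges::start(ub) - 1L,
    end = rep(start0, nb) + IRanges::end(ub))
  thick <- gr$thick
  has_cds <- !is.null(thick) & IRanges::width(thick) > 0L
  tr <- data.table::data.table(
    transcript_id = ids,
    chrom = chrom0,
    strand = as.character(GenomicRanges::strand(gr)),
    cds_start = ifelse(has_cds, IRanges::start(thick) - 1L, NA_integer_),
    cds_end = ifelse(has_cds, IRanges::end(thick), NA_integer_),
    source = source,
    support = if (!is.null(gr$score) && !anyNA(gr$score) && all(gr$score >= 1))
      as.integer(gr$score) else 1L)
  build_checked_ts(tr, bl)
}

read_transcripts_gtf <- function(path, source) {
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  if (length(ex) == 0L) stopf("GTF contains no exon features")
  if (any(is.na(ex$transcript_id))) stopf("GTF exon without transcript_id")
  bl <- data.table::data.table(
    transcript_id = ex$transcript_id,
    start = GenomicRanges::start(ex) - 1L,
    end = GenomicRanges::end(ex))
  meta <- data.table::data.table(
    transcript_id = ex$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    gene_id = if (!is.null(ex$gene_id)) ex$gene_id else NA_character_,
    src = if (!is.null(ex$source)) as.character(ex$source) else source,
    support = if (!is.null(ex$support)) suppressWarnings(as.integer(ex$support))
      else NA_integer_)
  tr <- meta[, list(chrom = chrom[1L], strand = strand[1L],
                    gene_id = gene_id[1L], source = src[1L],
                    support = support[1L]),
             by = transcript_id]
  tr[is.na(support) | support < 1L, support := 1L]
  cds <- gr[gr$type == "CDS"]
  if (length(cds)) {
    cdt <- data.table::data.table(
      transcript_id = cds$transcript_id,
      s = GenomicRanges::start(cds) - 1L, e = GenomicRanges::end(cds))
    cdt <- cdt[, list(cds_start = min(s), cds_end = max(e)), by = transcript_id]
    tr <- merge(tr, cdt, by = "transcript_id", all.x = TRUE)
  } else {
    tr[, `:=`(cds_start = NA_integer_, cds_end = NA_integer_)]
  }
  # any transcript feature without exons is an error
  trf <- gr[gr$type == "transcript"]
  orphan <- setdiff(trf$transcript_id, tr$transcript_id)
  if (length(orphan))
    stopf("GTF transcript with no exons: %s", orphan[1L])
  build_checked_ts(tr, bl)
}

# drop transcripts whose blocks overlap, logging them in attr "rejected"
build_checked_ts <- function(tr, bl) {
  data.table::setkey(bl, transcript_id, start)
  bad <- bl[, list(bad = .N > 1L && any(start[-1L] - end[-.N] < 0L)),
            by = transcript_id][bad == TRUE, transcript_id]
  if (length(bad)) {
    warning(sprintf("rejected %d transcript(s) with overlapping blocks", length(bad)))
    tr <- tr[!transcript_id %in% bad]
    bl <- bl[!transcript_id %in% bad]
  }
  # merge abutting blocks (GTF rounding artifacts)
  ts <- transcript_set(tr, bl)
  attr(ts, "rejected") <- bad
  ts
}

#' Write transcript models to BED12 or GTF
#'
#' Output is deterministically ordered by (chrom, start, transcript_id).
#' BED12 carries the CDS as thickStart/thickEnd and `support` as the score;
#' GTF carries `gene_id`, `transcript_id`, `source` and `support`
#' attributes, so a GTF round-trip preserves the full model.
#'
#' @param ts a [transcript_set()].
#' @param path output file.
#' @param format `"bed"` or `"gtf"`.
#' @export
write_transcripts <- function(ts, path, format = c("bed", "gtf")) {
  format <- match.arg(format)
  tr <- data.table::copy(ts$transcripts)
  data.table::setorder(tr, chrom, start, transcript_id)
  if (nrow(tr) == 0L) {
    writeLines(character(), path)
    return(invisible(path))
  }
  bl <- ts$blocks
  if (format == "bed") {
    gr <- GenomicRanges::GRanges(
      tr$chrom, IRanges::IRanges(tr$start + 1L, tr$end), strand = tr$strand)
    gr$name <- tr$transcript_id
    gr$score <- tr$support
    has_cds <- !is.na(tr$cds_start)
    gr$thick <- IRanges::IRanges(
      start = ifelse(has_cds, tr$cds_start + 1L, tr$start + 1L),
      end = ifelse(has_cds, tr$cds_end, tr$start))
    blo <- bl[data.table::data.table(transcript_id = tr$transcript_id),
              on = "transcript_id"]
    off <- rep(tr$start, tr$n_blocks)
    rel <- IRanges::IRanges(blo$start - off + 1L, blo$end - off)
    gr$blocks <- S4Vectors::splitAsList(
      rel, factor(blo$transcript_id, levels = tr$transcript_id))
    rtracklayer::export(gr, path, format = "bed")
  } else {
    blo <- bl[data.table::data.table(transcript_id = tr$transcript_id),
              on = "transcript_id"]
    idx <- match(blo$transcript_id, tr$transcript_id)
    feat <- function(chrom, s, e, strand, type, i) {
      g <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s + 1L, e),
                                  strand = strand)
      g$type <- type
      g$source <- tr$source[i]
      g$phase <- if (type == "CDS") 0L else NA_integer_
      g$gene_id <- ifelse(is.na(tr$gene_id[i]), tr$transcript_id[i], tr$gene_id[i])
      g$transcript_id <- tr$transcript_id[i]
      g$support <- as.character(tr$support[i])
      g
    }
    gt <- feat(tr$chrom, tr$start, tr$end, tr$strand, "transcript", seq_len(nrow(tr)))
    ge <- feat(tr$chrom[idx], blo$start, blo$end, tr$strand[idx], "exon", idx)
    parts <- list(gt, ge)
    has_cds <- which(!is.na(tr$cds_start))
    if (length(has_cds))
      parts <- c(parts, list(feat(tr$chrom[has_cds], tr$cds_start[has_cds],
                                  tr$cds_end[has_cds], tr$strand[has_cds],
                                  "CDS", has_cds)))
    gr <- do.call(c, parts)
    ord <- order(match(gr$transcript_id, tr$transcript_id),
                 match(as.character(gr$type), c("transcript", "exon", "CDS")),
                 GenomicRanges::start(gr))
    rtracklayer::export(gr[ord], path, format = "gtf")
  }
  invisible(path)
}

#' Splice junctions of transcript models
#'
#' One row per intron of every multi-exon model, with the canonical
#' junction `key` used throughout the package.
#'
#' @param ts a [transcript_set()].
#' @return data.table with transcript_id, chrom, strand, intron_start,
#'   intron_end, key.
#' @export
ts_junctions <- function(ts) {
  bl <- ts$blocks
  n <- bl[, .N, by = transcript_id]
  multi <- n[N > 1L, transcript_id]
  if (!length(multi)) {
    out <- data.table::data.table(transcript_id = character(),
                                  chrom = character(), strand = character(),
                                  intron_start = integer(),
                                  intron_end = integer())
    out[, key := character()]
    return(out)
  }
  b <- bl[transcript_id %in% multi]
  j <- b[, list(intron_start = end[-.N], intron_end = start[-1L]),
         by = transcript_id]
  j <- merge(j, ts$transcripts[, c("transcript_id", "chrom", "strand")],
             by = "transcript_id", sort = FALSE)
  j[, key := junction_key(chrom, strand, intron_start, intron_end)]
  j
}

# one chain string per transcript ("" for mono-exon)
ts_chain <- function(ts) {
  j <- ts_junctions(ts)
  ch <- j[, list(chain = paste(sprintf("%d-%d", intron_start, intron_end),
                               collapse = ";")), by = transcript_id]
  out <- merge(ts$transcripts[, c("transcript_id", "chrom", "strand")],
               ch, by = "transcript_id", all.x = TRUE, sort = FALSE)
  out[is.na(chain), chain := ""]
  out
}

# exonic length per transcript
ts_exonic_length <- function(ts) {
  ts$blocks[, list(exonic_len = sum(end - start)), by = transcript_id]
}

#' Transcription-order end positions of transcript models
#'
#' @param ts a [transcript_set()].
#' @return data.table with transcript_id, chrom, strand, tx_start, tx_end
#'   (0-based base coordinates; on "-" models tx_start > tx_end).
#' @export
ts_tx_ends <- function(ts) {
  tr <- ts$transcripts
  data.table::data.table(
    transcript_id = tr$transcript_id, chrom = tr$chrom, strand = tr$strand,
    tx_start = ifelse(tr$strand == "+", tr$start, tr$end - 1L),
    tx_end = ifelse(tr$strand == "+", tr$end - 1L, tr$start))
}
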