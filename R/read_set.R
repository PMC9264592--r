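#' Mapped long-read alignments
#'
#' A `read_set` holds mapped long reads at alignment level: per-read exon
#' blocks on the genome (0-based half-open, forward strand) plus located
#' mismatch events (substitutions, insertions, deletions) and a cap-capture
#' flag marking reads from 5'-cap-enriched libraries. It is the common input
#' of the junction-evidence and end-site modules.
#'
#' @param reads data.frame with columns `read_id`, `library_id`, `chrom`,
#'   `strand` ("+"/"-"), `cap` (logical).
#' @param blocks data.frame with columns `read_id`, `start`, `end`
#'   (0-based half-open exon blocks, sorted and non-overlapping per read,
#'   separated by gaps of at least 1 nt which are the read's introns).
#' @param mismatches data.frame with columns `read_id`, `pos`, `kind`
#'   (`"sub"`, `"ins"`, `"del"`), `len`. For insertions `pos` is the genomic
#'   base before which the inserted sequence sits; for deletions the event
#'   covers `[pos, pos + len)`.
#' @param validate check the block invariants (default TRUE).
#' @return an object of class `read_set`.
#' @export
read_set <- function(reads, blocks, mismatches = NULL, validate = TRUE) {
  reads <- data.table::as.data.table(reads)
  blocks <- data.table::as.data.table(blocks)
  if (is.null(mismatches) || nrow(mismatches) == 0L) {
    mismatches <- data.table::data.table(read_id = character(),
                                         pos = integer(),
                                         kind = character(),
                                         len = integer())
  } else {
    mismatches <- data.table::as.data.table(mismatches)
  }
  req <- function(df, cols, what) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) stopf("%s table lacks columns: %s", what,
                            paste(miss, collapse = ", "))
  }
  req(reads, c("read_id", "library_id", "chrom", "strand", "cap"), "reads")
  req(blocks, c("read_id", "start", "end"), "blocks")
  req(mismatches, c("read_id", "pos", "kind", "len"), "mismatches")
  blocks[, `:=`(start = as.integer(start), end = as.integer(end))]
  mismatches[, `:=`(pos = as.integer(pos), len = as.integer(len))]
  data.table::setkey(blocks, read_id, start)
  if (validate) {
    if (any(blocks$end <= blocks$start)) stopf("empty or inverted exon block")
    gap <- blocks[, list(bad = any(start[-1L] - end[-.N] < 1L)), by = read_id]
    if (any(gap$bad)) stopf("overlapping or abutting exon blocks within a read")
    if (!all(reads$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
    if (!all(mismatches$kind %in% c("sub", "ins", "del")))
      stopf("mismatch kind must be sub/ins/del")
    if (anyDuplicated(reads$read_id)) stopf("duplicate read_id")
  }
  span <- if (nrow(blocks) == 0L) {
    data.table::data.table(read_id = character(), start = integer(),
                           end = integer(), n_blocks = integer())
  } else {
    blocks[, list(start = min(start), end = max(end), n_blocks = .N),
           by = read_id]
  }
  reads <- merge(reads, span, by = "read_id", sort = FALSE)
  data.table::setkey(reads, chrom, start)
  structure(list(reads = reads, blocks = blocks, mismatches = mismatches),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d reads on %d chromosome(s), %d mismatch events\n",
              nrow(x$reads), length(unique(x$reads$chrom)),
              nrow(x$mismatches)))
  if (!is.null(attr(x, "skipped")) && attr(x, "skipped") > 0L)
    cat(sprintf("  (%d unmapped/secondary/supplementary records skipped)\n",
                attr(x, "skipped")))
  invisible(x)
}

#' Read mapped alignments
#'
#' Reads primary mapped alignments from a SAM/BAM file or from the package's
#' alignment TSV dialect (the format the simulator emits) into a
#' [read_set()]. For SAM/BAM, exon blocks are the match/deletion runs of the
#' CIGAR split at N operations; substitution events come from the MD tag
#' when present, otherwise from comparing aligned read bases to `genome`.
#' Unmapped, secondary and supplementary records are skipped and counted in
#' the `"skipped"` attribute.
#'
#' @param path SAM (.sam), BAM (.bam) or alignment TSV file.
#' @param genome optional `DNAStringSet`; required for SAM/BAM input whose
#'   records carry no MD tag.
#' @param format `"auto"` (by extension), `"sam"`, `"bam"` or `"tsv"`.
#' @return a [read_set()].
#' @export
read_alignments <- function(path, genome = NULL, format = c("auto", "sam", "bam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sam = "sam", bam = "bam", "tsv")
  }
  if (format == "tsv") read_alignments_tsv(path)
  else read_alignments_sam(path, genome, is_bam = (format == "bam"))
}

read_alignments_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character")
  need <- c("read_id", "library_id", "chrom", "strand", "cap", "blocks", "mismatches")
  if (!all(need %in% names(dt)))
    stopf("alignment TSV lacks columns: %s",
          paste(setdiff(need, names(dt)), collapse = ", "))
  parse_pairs <- function(s) {
    parts <- strsplit(s, ",", fixed = TRUE)
    n <- lengths(parts)
    flat <- unlist(parts, use.names = FALSE)
    se <- matrix(as.integer(unlist(strsplit(flat, "-", fixed = TRUE))),
                 ncol = 2L, byrow = TRUE)
    list(read_idx = rep(seq_along(s), n), start = se[, 1L], end = se[, 2L])
  }
  bl <- parse_pairs(dt$blocks)
  blocks <- data.table::data.table(read_id = dt$read_id[bl$read_idx],
                                   start = bl$start, end = bl$end)
  has_mm <- !(dt$mismatches %in% c("", "."))
  mism <- NULL
  if (any(has_mm)) {
    parts <- strsplit(dt$mismatches[has_mm], ";", fixed = TRUE)
    n <- lengths(parts)
    flat <- unlist(parts, use.names = FALSE)
    f <- matrix(unlist(strsplit(flat, ":", fixed = TRUE)), ncol = 3L, byrow = TRUE)
    mism <- data.table::data.table(read_id = rep(dt$read_id[has_mm], n),
                                   pos = as.integer(f[, 1L]),
                                   kind = f[, 2L],
                                   len = as.integer(f[, 3L]))
  }
  reads <- data.table::data.table(read_id = dt$read_id,
                                  library_id = dt$library_id,
                                  chrom = dt$chrom, strand = dt$strand,
                                  cap = dt$cap %in% c("TRUE", "true", "1"))
  read_set(reads, blocks, mism)
}

#' Write alignments in the package TSV dialect
#'
#' @param rs a [read_set()].
#' @param path output file.
#' @export
write_alignments <- function(rs, path) {
  stopifnot(inherits(rs, "read_set"))
  bl <- rs$blocks[, list(blocks = paste(sprintf("%d-%d", start, end),
                                        collapse = ",")), by = read_id]
  mm <- rs$mismatches[, list(mismatches = paste(sprintf("%d:%s:%d", pos, kind, len),
                                                collapse = ";")), by = read_id]
  out <- merge(rs$reads[, c("read_id", "library_id", "chrom", "strand", "cap")],
               bl, by = "read_id", sort = FALSE)
  out <- merge(out, mm, by = "read_id", all.x = TRUE, sort = FALSE)
  out[is.na(mismatches), mismatches := "."]
  data.table::setorder(out, chrom, read_id)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

read_alignments_sam <- function(path, genome = NULL, is_bam = FALSE) {
  bam <- if (is_bam) path else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags, tag = "MD",
                                   what = c("qname", "flag", "seq", "rname"))
  ga <- GenomicAlignments::readGAlignments(bam, use.names = FALSE, param = param)
  # count skipped records (all minus primary mapped)
  total <- Rsamtools::countBam(bam)$records
  skipped <- total - length(ga)
  if (length(ga) == 0L) stopf("no primary mapped records in %s", path)
  chroms <- as.character(GenomicAlignments::seqnames(ga))
  if (!is.null(genome) && !all(chroms %in% names(genome)))
    stopf("alignment chromosome absent from genome: %s",
          paste(unique(setdiff(chroms, names(genome))), collapse = ", "))
  mc <- S4Vectors::mcols(ga)
  cig <- GenomicAlignments::cigar(ga)
  qw <- GenomicAlignments::qwidth(ga)
  seqlen <- Biostrings::width(mc$seq)
  ok <- seqlen == qw | seqlen == 0L
  if (any(!ok)) {
    warning(sprintf("%d record(s) with CIGAR/sequence length mismatch rejected",
                    sum(!ok)))
    skipped <- skipped + sum(!ok)
    ga <- ga[ok]; mc <- mc[ok, , drop = FALSE]
    cig <- cig[ok]; chroms <- chroms[ok]
  }
  starts <- GenomicAlignments::start(ga)
  strands <- as.character(GenomicAlignments::strand(ga))
  strands[strands == "*"] <- "+"
  ids <- mc$qname
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "/")

  blk <- GenomicAlignments::extractAlignmentRangesOnReference(cig, starts,
                                                              drop.D.ranges = FALSE)
  nb <- S4Vectors::elementNROWS(blk)
  ublk <- unlist(blk)
  blocks <- data.table::data.table(read_id = rep(ids, nb),
                                   start = IRanges::start(ublk) - 1L,
                                   end = IRanges::end(ublk))
  mism <- sam_mismatch_events(ids, chroms, starts, cig, mc$seq, mc$MD, genome)
  reads <- data.table::data.table(read_id = ids,
                                  library_id = "sam",
                                  chrom = chroms, strand = strands,
                                  cap = FALSE)
  rs <- read_set(reads, blocks, mism)
  attr(rs, "skipped") <- skipped
  rs
}

# substitution events from MD tags (preferred) or genome comparison;
# insertion/deletion events from CIGAR I/D operations
sam_mismatch_events <- function(ids, chroms, starts, cig, seqs, md, genome) {
  ev <- vector("list", length(ids))
  dr <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = starts,
                                                          ops = "D")
  ir <- GenomicAlignments::cigarRangesAlongReferenceSpace(cig, pos = starts,
                                                          ops = "I")
  il <- GenomicAlignments::cigarRangesAlongQuerySpace(cig, ops = "I")
  for (i in seq_along(ids)) {
    events <- list()
    d <- dr[[i]]
    if (length(d))
      events$del <- data.table::data.table(pos = IRanges::start(d) - 1L,
                                           kind = "del", len = IRanges::width(d))
    ins <- ir[[i]]
    if (length(ins))
      events$ins <- data.table::data.table(pos = IRanges::start(ins) - 1L,
                                           kind = "ins",
                                           len = IRanges::width(il[[i]]))
    subs <- if (!is.null(md) && !is.na(md[i])) {
      md_substitutions(md[i], cig[i], starts[i])
    } else if (!is.null(genome)) {
      layered <- as.character(GenomicAlignments::sequenceLayer(
        seqs[i], cig[i], from = "query", to = "reference",
        D.letter = "-", N.letter = "."))
      cmp_substitutions(layered, chroms[i], starts[i], genome)
    } else {
      stopf("record %s has no MD tag and no genome was supplied", ids[i])
    }
    if (!is.null(subs) && nrow(subs)) events$sub <- subs
    if (length(events)) {
      e <- data.table::rbindlist(events)
      e[, read_id := ids[i]]
      ev[[i]] <- e
    }
  }
  out <- data.table::rbindlist(ev)
  if (nrow(out)) out[, c("read_id", "pos", "kind", "len"), with = FALSE] else NULL
}

# genomic positions covered by M and D CIGAR ops, in order (the MD tag's
# coordinate space)
md_space_positions <- function(cigar, pos) {
  r <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X", "D"))[[1L]]
  r <- r[order(IRanges::start(r))]
  unlist(lapply(seq_along(r), function(j) {
    seq.int(IRanges::start(r)[j], IRanges::end(r)[j])
  })) - 1L
}

md_substitutions <- function(md, cigar, pos) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1L]]
  gpos <- md_space_positions(cigar, pos)
  i <- 1L
  out_pos <- integer()
  for (tk in toks) {
    if (grepl("^[0-9]+$", tk)) {
      i <- i + as.integer(tk)
    } else if (startsWith(tk, "^")) {
      i <- i + nchar(tk) - 1L
    } else {
      out_pos <- c(out_pos, gpos[i])
      i <- i + 1L
    }
  }
  if (!length(out_pos)) return(NULL)
  data.table::data.table(pos = out_pos, kind = "sub", len = 1L)
}

cmp_substitutions <- function(layered, chrom, pos, genome) {
  ref <- genome_fetch(genome, chrom, pos - 1L, pos - 1L + nchar(layered))
  a <- strsplit(layered, "")[[1L]]
  b <- strsplit(ref, "")[[1L]]
  hit <- which(a != b & a != "-" & a != "." & a != "N" & b != "N")
  if (!length(hit)) return(NULL)
  data.table::data.table(pos = pos - 1L + hit - 1L, kind = "sub", len = 1L)
}
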