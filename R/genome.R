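#' Read a genome from FASTA
#'
#' Loads all records of a FASTA file into a `DNAStringSet`. Sequences are
#' uppercased and RNA-style U is normalised to T; record names are trimmed
#' at the first whitespace. All genomic coordinates used by this package are
#' 0-based half-open on the forward strand.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per chromosome.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stopf("FASTA file not found: %s", path)
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stopf("malformed FASTA '%s': %s", path, conditionMessage(e))
  )
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stopf("duplicate chromosome id in %s: %s", path,
          names(seqs)[duplicated(names(seqs))][1L])
  # readDNAStringSet already maps U->T; uppercase lowercase (soft-masked) runs
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  seqs
}

#' @rdname read_genome
#' @param genome a `DNAStringSet`.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' @rdname read_genome
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Fetch genomic sequence
#'
#' Extracts `[start, end)` (0-based half-open, forward strand) from one
#' chromosome. Vectorised over `start`/`end`; an empty interval returns "".
#'
#' @param genome a `DNAStringSet` from [read_genome()].
#' @param chrom chromosome id (scalar or vector recycled against starts).
#' @param start,end 0-based half-open bounds, `0 <= start <= end <= length`.
#' @return character vector of sequences.
#' @export
genome_fetch <- function(genome, chrom, start, end) {
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(chrom, n); start <- rep_len(start, n); end <- rep_len(end, n)
  if (!all(chrom %in% names(genome)))
    stopf("chromosome absent from genome: %s",
          paste(unique(setdiff(chrom, names(genome))), collapse = ", "))
  lens <- genome_lengths(genome)[chrom]
  if (any(start < 0L) || any(end > lens) || any(start > end))
    stopf("interval out of bounds for genome fetch")
  out <- character(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    ir <- IRanges::IRanges(start = start[i] + 1L, end = end[i])
    out[i] <- as.character(Biostrings::extractAt(genome[[ch]], ir))
  }
  out
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (IUPAC letters allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  out <- x
  nz <- !is.na(x) & nchar(x) > 0L
  if (any(nz))
    out[nz] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[nz])))
  out
}
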