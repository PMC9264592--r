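# in-code fixtures shared across test files

# genome from literal sequences
make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

# a deterministic 300-nt toy chromosome: all C except where overridden
toy_chrom <- function(len = 300L, at = integer(), base = character()) {
  x <- rep("C", len)
  x[at + 1L] <- base
  paste(x, collapse = "")
}

# quick read_set builder: blocks as list of c(start, end) matrices
make_reads <- function(..., mismatches = NULL) {
  specs <- list(...)
  reads <- data.table::rbindlist(lapply(specs, function(s)
    data.table::data.table(read_id = s$id,
                           library_id = s$lib %||% "lib1",
                           chrom = s$chrom %||% "chr1",
                           strand = s$strand %||% "+",
                           cap = isTRUE(s$cap))))
  blocks <- data.table::rbindlist(lapply(specs, function(s)
    data.table::data.table(read_id = s$id,
                           start = s$blocks[, 1L], end = s$blocks[, 2L])))
  read_set(reads, blocks, mismatches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# transcript_set builder: models as list(id=, chrom=, strand=, blocks=matrix,
# cds=c(s,e) or NULL, gene=, source=, support=)
make_ts <- function(...) {
  specs <- list(...)
  tr <- data.table::rbindlist(lapply(specs, function(s)
    data.table::data.table(transcript_id = s$id,
                           gene_id = s$gene %||% NA_character_,
                           chrom = s$chrom %||% "chr1",
                           strand = s$strand %||% "+",
                           cds_start = if (is.null(s$cds)) NA_integer_ else s$cds[1L],
                           cds_end = if (is.null(s$cds)) NA_integer_ else s$cds[2L],
                           source = s$source %||% "other",
                           support = s$support %||% 1L)))
  bl <- data.table::rbindlist(lapply(specs, function(s)
    data.table::data.table(transcript_id = s$id,
                           start = s$blocks[, 1L], end = s$blocks[, 2L])))
  transcript_set(tr, bl)
}

blocks2 <- function(...) matrix(c(...), ncol = 2L, byrow = TRUE)

# independent exact binomial point mass via log-factorials
oracle_binom_pmf <- function(k, m, p) {
  lf <- function(x) lgamma(x + 1)
  t1 <- if (k == 0L) 0 else k * log(p)
  t2 <- if (m - k == 0L) 0 else (m - k) * log1p(-p)
  exp(lf(m) - lf(k) - lf(m - k) + t1 + t2)
}

# small default-parameter object shared by tests
P <- isocurate::pipeline_params()
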