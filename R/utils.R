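# internal helpers shared across modules

# round half away from zero (printed summaries use commercial rounding,
# not the IEEE round-half-even of base round())
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  out <- sign(x) * floor(abs(x) * f + 0.5) / f
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical junction key; one string per junction, used as identity everywhere
junction_key <- function(chrom, strand, intron_start, intron_end) {
  paste(chrom, strand, intron_start, intron_end, sep = ":")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# connected components over an edge list of integer vertex ids 1..n
components_of <- function(n, from, to) {
  if (length(from) == 0L) return(seq_len(n))
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::components(g)$membership
}
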