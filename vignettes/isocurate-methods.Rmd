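---
title: "Curating long-read transcriptomes: models and choices"
author: "isocurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating long-read transcriptomes: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isocurate)
```

# Scope and data model

`isocurate` curates transcript models from *mapped* long cDNA reads. It
deliberately starts downstream of basecalling and alignment: its input is
a `read_set` — per-read exon blocks on the genome plus located mismatch
events (substitutions, insertions, deletions) and a cap-capture flag — and
its claims are therefore conditional on the mapper's block structure.
Introns are exactly the gaps between consecutive blocks; the package never
second-guesses where the aligner placed a gap, it only decides whether the
local evidence supports it.

All coordinates are 0-based half-open on the forward genome strand, with
strand stored separately; BED12 is the native interchange format and GTF
is converted at the boundary. One convention everywhere removes the
off-by-one drift that plagues multi-format pipelines.

# Junction evidence and the high-confidence rule

Sequencing errors near a splice junction cause "edge wander": the aligner
slides the intron gap a few bases and compensates with mismatches packed
against the new junction. The observable signature is therefore local: a
false junction's supporting reads all carry mismatches within a few
nucleotides of it, while a correct junction is usually hit by at least one
locally clean read.

For every junction of every read we record mismatch offsets 1..30 nt into
the adjacent exons, in transcription order. Offsets are exonic-side only —
the intron is absent from the read, so there is nothing to measure on the
intron side. Insertions sit between two bases and take the offset of the
base nearer the junction; deletions disqualify every position their
genomic footprint covers, since a deletion through the near-window is as
diagnostic as a substitution in it.

A junction is high confidence iff

1. its intron motif, read on the transcribed strand, is canonical
   (GT-AG, GC-AG, AT-AC — the standard U2/U12 set, configurable), and
2. at least one supporting read has **zero** events at offsets 1..10 on
   both sides (`sj_clean_window`, 10 nt).

The rule is junction-centric on purpose: discarding whole reads for one
bad junction throws away their good junctions, and reads with errors near
a correct junction are rescued by any clean sibling. Non-canonical motifs
are tested first, so reject reasons are deterministic.

For descriptive profiles (and the retention curve) each junction is
represented by its best observation — fewest mismatch positions in the
60-nt region, ties broken by fewest within ±10, then lexicographic read
id so re-runs are identical. Note one subtlety: the high-confidence rule
quantifies over *all* observations, while the retention curve looks at
the *best* one. The two coincide unless a junction's minimum-total read
is near-dirty while a higher-total read is near-clean, which is rare
enough that the cross-check test on simulated data holds, but the
definitions are intentionally not interchangeable.

## Splice-site PWM

Sites are scored with position weight matrices over conventional windows
(donor: 3 exonic + 10 intronic nt; acceptor: 14 intronic + 3 exonic),
trained by default on the high-confidence set with a pseudocount of 1,
and affinely rescaled so the best achievable sequence scores 100 and the
worst 0; 65 is the working threshold for a "good" site. The log-odds
background is **uniform** by default: with a uniform background the
matrix is a pure frequency model and the training consensus is provably
the top-scoring sequence, which keeps the 0–100 scale interpretable
("100 = the consensus"). A background equal to the training set's overall
base composition is available (`background = "training"`), but on skewed
compositions it can rank an unobserved rare base above the observed
consensus base, making "consensus scores 100" false — an unhelpful
property for a QC score. Windows containing N are excluded from training;
when scoring, an N contributes the position's minimum log-odds
(conservative). Degenerate matrices (max = min) score 100 by convention.

# Stratified end determination

Read 5' and 3' ends mix true TSS/TES with degradation ends. The two
regimes need different treatment:

* **Highly sequenced loci.** True sites are sampled repeatedly while
  degradation ends scatter. With m read ends over n distinct locations in
  a locus and the null that each end falls on any location equally
  (p = 1/n), the probability of k ends sharing a location is the binomial
  point mass Pr(k; m, p). A location is **significant** iff k > m/n and
  Pr(k; m, p) < `end_alpha` (0.05).
* **Sparsely sequenced loci.** No statistical call is possible; instead a
  location is **supported** iff ≥ `end_min_reads` (2) reads end within an
  11-nt sliding window (±`end_window_halfwidth` = 5 nt).

The boundary between regimes is *emergent*: the binomial test runs first
and the window rule applies only to locus/side combinations with no
significant call. No fixed read-count threshold is involved; loci migrate
between strata as coverage changes.

Numerical choices worth stating:

* **Point mass, not tail.** Pr is the pmf exactly as the method defines
  it, not an upper-tail sum; `tail = TRUE` computes P(X ≥ k) for
  sensitivity analysis. For the k > m/n locations that can pass the
  significance rule the two orderings agree closely, and the pmf is the
  stated criterion. With n = 1, Pr(m; m, 1) = 1, so a single-location
  locus can never be significant — it falls to the supported stratum,
  which is the correct behaviour for the degenerate case.
* **Window collapse.** Overlapping supported candidates (within 5 nt)
  collapse to the position with the highest own count, ties to the
  transcription-order 5'-most, guaranteeing reported supported calls are
  ≥ 6 nt apart. The collapse rule is a package choice; some stacking rule
  is needed and this one is deterministic and favours the sharpest peak.
* **Off-priming.** Before 3' calling, an end is removed if ≥
  `offprime_min_A` (6) of the `offprime_window` (10) genomic nucleotides
  immediately downstream in transcription order are A on the transcribed
  strand. "Followed by poly(A)" needs quantification; 6-of-10 tolerates
  scattered non-A while still requiring a primable run, and both numbers
  are parameters. At chromosome ends the threshold is prorated to the
  available window. m and n are recomputed after removal, so the binomial
  operates on the cleaned tally (the removed ends were never candidate
  TES, and leaving them in would deflate p for real sites).
* **Cap filter.** Only cap-enriched (e.g. Teloprime) reads enter 5'
  tallies; uncaptured libraries systematically under-represent true 5'
  ends. All reads enter 3' tallies.
* **Rounding.** Printed per-locus means round half away from zero to two
  decimals, matching the convention of the summary tables they reproduce.

Each significant or supported call seeds a ±`region_halfwidth` (50 nt)
high-confidence region, inclusive on both edges, clipped to the
chromosome and never merged with neighbours.

## Loci

The per-gene framing needs a locus definition. Default: single-linkage
clustering of same-strand reads whose exonic footprints overlap ≥ 1 nt —
annotation-free, so novel genes are first-class. With an annotation,
reads are assigned to the gene with maximal exonic overlap and only
unassigned reads are clustered. The two modes can split or lump loci
differently at overlapping genes; results are reported per locus either
way.

# Transcript building

The exact collapse groups reads only when chromosome, strand, junction
chain, start and end all agree, preserving 1-nt UTR differences; this
keeps the raw isoform inventory faithful before any windowed merging.
After SJ and end filtering (a model needs every junction high-confidence
and both transcription-order ends inside called regions, with reasons
`no_tss`/`no_tes`/`neither` recorded), the high-level collapse groups
models with identical chains and both ends within
`collapse_wobble_high` (50) nt. Grouping is greedy, seeded by descending
support (ties: longer span, then leftmost), and the representative keeps
the seed's coordinates with support summed. A greedy seed was chosen over
transitive pairwise merging because chains of 50-nt steps would otherwise
connect ends arbitrarily far apart; seeding by support makes the
representative the best-evidenced end pair, and the procedure is
idempotent. Mono-exon models additionally require ≥ 1 nt of overlap to
group. Junction variants as small as NAGNAG acceptor shifts are never
merged, because chains must match exactly.

Rescue: a model removed by end filtering is retained anyway when ≥
`rescue_overlap` (50 %) of its exonic length overlaps a same-strand
annotated transcript — coverage insurance for genes the read data cannot
call ends in. The rule is applied per transcript and then extended to all
removed models of a rescued locus (disable with `locus_extend = FALSE`);
the locus extension mirrors gene-level rescue while the per-transcript
rule keeps the criterion local.

## RTD merging

Short-read assemblies contribute in two ways only: transcripts with ≥ 1
junction absent from the growing junction set (processed sequentially, so
a junction admitted from one source blocks re-admission from the next)
and transcripts on loci with zero same-strand span overlap with the
long-read set. "Novel locus" is strict zero overlap — the conservative
reading; a sub-threshold-overlap variant is a one-line change but admits
fragments of existing genes. During the merge the long-read set holds
end-coordinate priority: an addition with an identical chain and both
ends within 50 nt is absorbed (its coordinates discarded), and no
long-read model's coordinates are ever altered.

# Motif validation

Called sites are validated by scanning IUPAC motifs over ±500 nt oriented
flanks (minus-strand flanks reverse-complemented; edge sites N-padded,
and N never matches). Overlapping matches are counted by default.
Controls are equal-sized uniform random site sets (length-weighted
chromosome choice, both strands), seeded for reproducibility. Enrichment
is a two-proportion z-test with pooled variance and no continuity
correction, floored at the smallest representable double and printed as
"< 2.2e-16" below that conventional threshold. The default motif set
(TATA = TATAWAW, Inr = YYANWYY, Y-patch = YYYYYYYY, Kozak = RNNATGG,
PAS = AATAAA, CFIm = TGTA) is a deliberately generic collection of
promoter/terminator elements; any analysis-grade set should be supplied
via the motif TSV, and nothing downstream depends on the defaults.

# Annotation

Gene assignment uses the ">30 % of either party" exonic-overlap rule on
the same strand: denominators are both the model's and the reference
transcript's exonic length, so a short model inside a long gene and a
long model spanning a short gene both match. Two or more matched genes
concatenate in genome order ("AT1G18020-AT1G18030"-style), which is how
read-through (chimeric) transcripts are surfaced rather than suppressed.
Unmatched models cluster into novel loci numbered "G0001…" in genome
order — deterministic across re-runs.

The ORF finder returns the longest ATG-initiated reading frame on the
transcribed strand; with no in-frame stop it extends to the last full
codon and flags the absence. It is plumbing for the non-stop rules, not a
gene predictor. Non-stop RNAs then require, in order: CDS end within 3 nt
of the transcript end (strict <, i.e. gap 0–2); no in-frame stop codon
ending in the last 5 nt; the gene's most distal TES more than 100 nt
beyond the transcript end (strict >); and a protein-coding gene (some
transcript with ≥ 100 codons). The distal TES defaults to the RTD itself
(self-contained; a reference can be supplied), and "within"/"larger than"
are read strictly — both directions are parameters, so the opposite
reading is one argument away.

# The simulator: what it does and does not emulate

The generator builds a random-sequence genome and non-overlapping gene
models (15 % mono-exonic; 2–8 exons of 80–300 nt; introns 60–200 nt;
terminal exons 250–400 nt), embeds canonical splice motifs at every
intron boundary (5 % GC-AG, 2 % AT-AC by default), gives 30 % of genes an
alternative TSS and/or TES 120 nt from the primary with 70/30 usage, and
plants an 8-A run mid-transcript in 40 % of genes. Reads (30 % of genes
low-coverage with 1–6 reads; the rest log-uniform 7–2000, ~50k reads at
the default 200 genes) then suffer exactly the corruptions the pipeline
targets: 1 % substitutions and 0.25 % indels; 5 % junction wander (one
junction shifted ≤ 4 nt with compensating near-junction mismatches — the
precise failure signature the SJ filter detects); 30 % 5' and 10 % 3'
degradation (60 nt + exponential mean 240); 50 % off-priming at A-run
genes; 80 % cap capture; ±1 nt end jitter for the stochasticity of real
TSS/TES. Every draw descends from one seed, so outputs are byte-identical
across runs.

Two deliberate idealisations matter for interpreting green tests. First,
reads are emitted at alignment level, so mapper-specific artifacts other
than the modelled junction wander (multi-mapping, soft-clipping,
systematic homopolymer indels) are absent; passing tests certify the
curation logic, not robustness to an arbitrary aligner. Second, a true
TES immediately followed by a templated A-run is indistinguishable from
off-priming *by definition of the filter*, so the generator never creates
such ambiguous truth sites (the downstream 10-nt window of a true TES is
kept below the 6-A threshold). On real data such sites exist and are the
filter's irreducible false-removal mode — roughly the per-site chance of
a ≥6-of-10 A window, ~0.4 % on random sequence.

Evaluation conventions: junction recall is measured against true
junctions with at least one *clean-supporting* read (no event within
±10 nt on either side) — junctions whose every read is locally dirty are
unrecoverable under the stated rule and are labelled as such in the truth
table, not counted against the caller. End recall is measured on the
dominant site per gene/side with ≥ 2 concordant reads, within ±50 nt.
Minority alternative sites at moderate coverage are genuinely ambiguous
under the stated criteria (k > m/n can only hold for one site of a pair)
and are reported but not scored.

# Problem sizes and runtime

The shipped test-suite exercises unit fixtures of a few reads plus
simulations of 15–40 genes, and one default-sized study (200 genes, ~50k
reads) for the recovery criteria; the whole suite runs in about a minute
on one CPU, and `scripts/acceptance.R` (default study + null run +
arithmetic checks) in about 45 seconds. These sizes were chosen so the
binomial stratum is well populated (hundreds of loci with 7–2000 reads)
while iteration stays interactive.

# Known limitations

* Loci are built by overlap clustering; interleaved or antisense-nested
  genes sharing exonic sequence on one strand will be lumped.
* The supported-end stratum will endorse two concordant degradation ends
  at a low-coverage locus; this is inherent to the 2-read rule, and such
  calls carry `status = "supported"` so they can be filtered downstream.
* The binomial null assumes exchangeable locations within a locus;
  strongly position-dependent degradation (e.g. 5' bias from cap
  escape) is only partly absorbed by the k > m/n guard.
* The PWM is a per-position independence model scored 0–100; it ranks
  splice-site strength but is not calibrated to splicing efficiency.
* `read_alignments` trusts primary alignments; chimeric or
  supplementary-only reads are skipped, not repaired.
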