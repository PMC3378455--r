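---
title: "Methods: de novo transcriptome assembly, annotation and expression profiling with denovokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: de novo transcriptome assembly, annotation and expression profiling with denovokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

denovokit re-creates, as one tested R toolkit, the computational path of an
early short-read transcriptome study of a non-model plant: paired-end 36 bp
reads from two growth temperatures are quality-filtered, assembled de novo
over a sweep of k-mer sizes, reduced to a non-redundant transcript set,
grouped into "unique genes" by shared best similarity hits, annotated with
GO/EC/KEGG terms and GO slims, quantified by RPKM in both conditions, binned
into fold-change classes, and profiled for SSR markers and GC content.
External engines of the original workflow (the production assembler, the
similarity-search program, the live annotation databases) are out of scope:
similarity hits and annotation tables are consumed as tabular inputs, and
the assembler here is a deliberately transparent de Bruijn unitig builder
meant for desk-scale experiments, not a production scaffolder.

Because the study's raw reads and era-specific databases are not
reproducible offline, verification rests on (a) property-based tests, (b)
planted-truth recovery on synthetic data from the package's own seeded
generators, and (c) oracle equivalence against independent
implementations. Every stage can therefore be exercised end to end without
any external file.

# Read filtering

Reads arrive as paired FASTQ (phred+33 by default) or paired qseq
(phred+64, the platform convention of the study's era; `.` is read as N).
Filtering proceeds per mate:

1. a fixed 3' tail trim (`tail_trim`, default 3 bp — 36 bp reads keep 33
   bases, matching the study's handling of error-prone 3' ends);
2. adapter read-through removal: the longest overlap of an adapter prefix
   with the read suffix of length ≥ `adapter_min_overlap` (5) and mismatch
   fraction ≤ `adapter_max_mismatch_rate` (0.10) is trimmed off;
3. survival rules, applied in a fixed order — post-tail-trim length ≥
   `min_read_len` (20), adapter trim not leaving the mate shorter than
   that, mean phred ≥ `mean_quality_cutoff` (20), and (optionally) median
   dataset frequency of the mate's k-mers ≥ `kmer_min_freq` (2 at k = 23).

A pair is kept only when both mates pass; a dropped pair is attributed to
the first failing rule, so `pairs_out + Σ dropped == pairs_in` holds by
construction and is asserted at run time. The original filtering tool's
exact rule order is unpublished; the order above is this package's declared
convention. Mean phred per read (rather than a per-base minimum) is the
quality statistic, the plainest reading of "average read quality", and the
median (not minimum) k-mer frequency makes the k-mer rule robust to a
single error k-mer.

The Recommender emulation profiles mean quality per position (pooled over
both mates) and suggests (i) a trim point — the first position where the
positional mean falls below a threshold (default Q20) for at least two
consecutive positions, a two-in-a-row rule that ignores single-position
dips — and (ii) the largest integer cutoff retaining a target fraction
(default 75%) of reads by mean quality, found by scanning all integer
cutoffs.

# Assembly and k selection

`count_kmers()` counts all A/C/G/T k-mers, canonically (k-mer pooled with
its reverse complement under the lexicographically smaller string) for
assembly. `build_unitigs()` discards k-mers below `min_count` (default 2,
the package's reading of "high-frequency k-mers"), builds the de Bruijn
graph on (k−1)-mer nodes with both strands present, and emits every maximal
non-branching path once, under the lexicographically smaller of its two
strands. Coverage is the mean count of the path's k-mers (fold depth, a
plain number; one of the study's tables labels the same column as a
percentage — the unit here is deliberately fold depth). Contigs shorter
than 100 bp are dropped, the study's stated cutoff. No bubble popping, tip
clipping, pair-distance scaffolding or gap filling is attempted: a 50/50
variant breaks the path at its branch by design.

`kmer_sweep()` assembles at each k (pipeline default 19–29, step 2) and
`select_k()` picks the k maximizing average contig length, with ties broken
by the percentage of contigs over 1 kb and then the smaller k. This is a
declared formalization of the study's informal "balance" criterion; on the
six-row reference stat table shipped with the package it selects k = 23.

# Redundancy reduction and gene grouping

`cluster_by_identity()` is greedy and longest-first: sequences are visited
in decreasing length order and join the best-matching existing cluster at
or above the identity threshold, else found a new one, so representatives
are always their cluster's longest member. Identity is matching columns of
a global alignment of the shorter sequence (locally anchored in the longer,
both strands tried) divided by the shorter length — the convention of the
clustering-tool family the study used; the alignment itself comes from
Biostrings' pairwise aligner. A shared 10-mer pre-screen skips hopeless
pairs; it is purely an optimization and the tests hold it to the all-pairs
answer. The two-stage 95% → 90% cascade is exposed as
`cluster_cascade(seqs, c(0.95, 0.90))`.

`merge_terminal_overlaps()` iteratively merges pairs whose ungapped
suffix/prefix overlap (any of the four end-to-end orientations up to
strand) spans ≥ 40 bp at ≥ 90% identity, longest overlap first in a fixed
(length, id) scan order; disagreeing overlap columns take the longer
sequence's base. Merging repeats to a fixed point, which the tests verify.

`select_best_hit()` keeps, per query, the hit with the highest bitscore
(ties: smaller e-value, then subject id) after an e-value cutoff — 1e-5 for
gene grouping, 1e-1 for annotation transfer, mirroring the study's two
presets. `group_by_subject()` partitions queries by best-hit subject; each
group is the study's "unique gene", represented by its longest member.
Whether member hits overlap on the subject is recorded in the group table
but deliberately not acted on: the source text is ambiguous about whether
grouping required non-overlapping subject regions, and grouping on the
shared subject alone is the weaker, declared choice.

# Annotation and enrichment

`six_frame_orfs()` reports, per frame, the longest stop-free codon run
(stop-to-stop, no initiator required — the downstream domain-scan use case
does not need Met starts), with a 20-aa default floor since the study
states no length floor. Spans are mapped back to forward-strand 1-based
coordinates.

`transfer_annotations()` copies the best subject's GO/EC/KEGG sets to each
gene; `classify_go_slim()` consumes a precomputed child-to-slim table
(ontology-graph traversal is out of scope), counting each gene at most once
per slim but allowing membership in several, with an explicit `"unmapped"`
bucket.

`enrich_terms()` computes, per term with at least one study gene, the
one-sided (over-representation) upper-tail hypergeometric probability via
`stats::phyper`, Bonferroni-corrected over the number of tested terms (m =
terms with k ≥ 1, the common enrichment-tool convention; the study names
only the correction). The tests hold the tail to an explicit combinatorial
enumeration for every population size up to 25 at 1e-12, and check type-I
calibration on uniformly random study sets. Because the hypergeometric is
discrete, P(p ≤ α) sits slightly below α for any finite population; the
calibration experiment therefore uses a population of 2,000 genes, study
sets of 1,000 and term sizes of 800–1,200 — large enough that the
achievable-p grid near 0.05 is fine — with 10 terms × 200 replicates.

# Read mapping, RPKM and fold classes

`map_reads()` finds every placement of every read on both strands with at
most `max_mismatches` (default 2, the study's setting). The engine splits
each read into `max_mismatches + 1` segments; by pigeonhole, any qualifying
placement leaves one segment error-free, so an 11-mer positional index
seeded at each segment start finds all candidates, which are verified by
full Hamming comparison. Reads shorter than 11 × (mismatches + 1) bases are
skipped and counted. A second, independent exhaustive engine scans every
(transcript, offset, strand); the suite requires bit-identical output from
both, plus agreement with Biostrings' mismatch-tolerant pattern matching on
spot checks. A read is uniquely mapped when exactly one placement attains
its best score.

RPKM is 1e9·C/(N·L) with C the unique-read count aggregated over a gene
group's members, L the representative's length, and N the condition's total
uniquely mapped reads — multi-mapped reads are excluded from both C and N
(the study counts "uniquely mapped reads"; the N convention is declared
here because the source leaves it open). Mates are mapped independently, so
a pair contributes up to two counted reads, the era-typical convention.
Transcripts outside every group are quantified as their own gene. Folds are
a/b ratios with a 0.5-RPKM pseudo-value applied only to zero sides, binned
into the six classes >10, (5,10], (2,5], (1,2], (0.5,1], ≤0.5 — the study
names only the endpoints; the interior boundaries are declared here — and
the fold ≥ 2 / fold ≤ 0.5 gene sets are emitted for enrichment.

# Markers

`find_ssrs()` reports every maximal perfect tandem repeat of unit size 1–5
meeting the canonical MISA-style thresholds 10/6/5/5/5 (the study prints no
thresholds; these are the defaults of the tool it names, configurable, with
a hexanucleotide class available but off by default). A repeat whose unit
is itself periodic is reported under its smallest period; compound or
interrupted repeats are not merged. Coordinates are 1-based inclusive.
`gc_content()` is (G+C)/(A+C+G+T) with ambiguity codes excluded from the
denominator, and `gc_profile()` bins per-sequence fractions at 10% width.

# The synthetic-data generator

The generator is first-class, seeded code; its defaults are the study
conditions the toolkit is tested under:

* transcripts: length ~ Normal(440, 250) truncated at 100 bp and GC target
  44.6%, the deposited set's scale; abundances log-normal (sdlog 1), a
  heavy-tailed shape typical of transcriptomes (the study states no
  abundance model);
* reads: 36 bp mates from ~Normal(200, 20) inserts, R2
  reverse-complemented; per-base qualities decay linearly (default Q38 →
  Q20) with Gaussian jitter (sd 2) clamped to [2, 41]; errors are drawn
  from the phred error probability unless a flat rate is given; with
  probability `adapter_rate` the insert is drawn shorter than the read so
  both mates run through into the adapter, always leaving ≥ 8 adapter
  bases so every planted contamination is detectable;
* families: `"fragment"` mode cuts a parent gene into members covering
  distinct regions (they share a best-hit subject but little sequence —
  the grouping scenario); `"copy"` mode emits the parent plus slightly
  shortened divergent copies (the identity-clustering scenario, where the
  intact parent is unambiguously the longest member). Divergence plants
  exactly round(rate × length) substitutions so "3% divergence" is the
  realized, not merely expected, divergence;
* planted SSRs are written in with their flanking bases forced off-period,
  so recovery at exact coordinates is well defined;
* hit tables give every family member a best hit to its parent's subject
  with region-derived subject intervals, optional strictly-worse decoys,
  and a 30% "unknown" fraction of singletons without hits, mirroring the
  study's no-hit share.

Two generator choices are worth flagging because they make otherwise
knife-edge checks well posed. First, reconstruction experiments use
*tiled* reads — evenly spaced starts at the requested depth, terminal
starts duplicated — because uniform-random starts at depth 30 do not
structurally guarantee k-mer continuity (a single ≥ 14 bp start gap breaks
a unitig) and terminal k-mers would otherwise fall below the frequency
cutoff. Second, the planted fold multiplier defaults to 2.5: a planted
fold of exactly 2.0 lies on the boundary of the (2,5] class, where
symmetric sampling noise makes measured class membership a coin flip, so
an exact-2 plant has no well-defined true class.

What the generator does not emulate: platform-specific error profiles
(errors are independent substitutions), indels, splice isoforms, polyA
tails, coverage biases, or chimeric fragments. Passing tests therefore
show algorithmic correctness under clean, known-truth conditions, not
robustness to every artifact of real libraries.

# Problem sizes and numerical choices

The suite and the acceptance script run, per invocation: mapper-oracle
equivalence on 50 transcripts (0.5–2 kb) × 2,000 reads with 0–3 injected
mismatches; hypergeometric enumeration over all populations to N = 25 plus
2,000 calibration p-values; SSR oracle equivalence on 500 × 1 kb sequences
with 50 planted repeats; reconstruction of 20 × 1 kb transcripts from
tiled 36 bp reads at depth 30 with k = 23; 40 planted families × 3 members
at 3% divergence; and 200 genes × ~200,000 pairs per condition for
fold-class recovery. These sizes keep a full run in the low minutes on one
CPU while leaving each check's failure modes visible.

Tie-breaks are deterministic everywhere (radix/C-locale ordering on ids and
sequences), trimming and filtering are order-independent, and pipeline
reruns with identical inputs, config and seed produce byte-identical
artifacts apart from the timing column of the log. Floating-point
mismatch-budget comparisons (adapter and overlap identity) add 1e-9 before
truncation so exact-boundary cases (e.g. 4 mismatches in a 40 bp overlap at
90%) land on the accepting side.

# Known limitations

The unitig assembler is a stand-in: real de novo assemblers use pair
distances, bubble resolution and coverage models this package deliberately
omits, so its contig sets on noisy data will be more fragmented. Greedy
identity clustering is order-dependent by design (longest first) and not a
bit-for-bit re-creation of any external tool. The enrichment test is
one-sided over-representation only. qseq support covers the 10- and
11-field dialects only, and gzip is the only compression handled.
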