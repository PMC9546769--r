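---
title: "Methods: simulating and quality-controlling 5' UMI reads"
author: "umi5p"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quality-controlling 5' UMI reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(umi5p)
```

# Scope

`umi5p` implements the bespoke computational steps around 5′ UMI reads in
template-switching scRNA-seq chemistries: motif-grammar UMI extraction
(including the read-2 rescue after intra-TSO tagmentation), detection and
filtering of strand-invasion artifacts, molecule counting with an
edit-distance diagnostic, per-cell SNP benchmarking against an exome
reference, and sensitivity statistics. It deliberately does **not**
align reads, call variants on real data, or normalise/cluster expression
matrices — it consumes alignments and call sets and emits counts and
reports. A ground-truth simulator stands in for sequencing data so every
guarantee is checkable.

# The motif grammars

A UMI read 1 starts with the TSO remnant
`adapter + UMI(8) + spacer + GGG`. The grammar anchors on `GG`, treating
the third guanosine as template: trimming removes the matched
`adapter-suffix + UMI + spacer + GG` exactly, and no additional leading
`G` is stripped. Two dialects are supported:

* `spacer` — adapter (full, or truncated by up to `len − 2` leading
  bases, so the minimum accepted suffix is 2 nt), 8-nt UMI, a fixed 5-nt
  spacer (default `CTAAC`), anchor `GG`;
* `ss3` — no spacer, minimum adapter suffix 4 nt (the deeper truncation
  search is unsafe without a spacer because the motif becomes too short
  to be specific).

Read-2 rescue matches an explicit adapter-suffix set (`GAGT`, `AGT`,
`GT` by default) followed by the same UMI/spacer/anchor layout, and swaps
the mates so the UMI-bearing cDNA is always mate 1 downstream. When both
mates match, read 1 wins: R1 is the designed configuration and R2 the
rescue, and a double match is overwhelmingly an R1 read whose mate
happens to mimic the short R2 prefix. Adapter, spacer and anchor matching
is exact; base qualities are ignored. Longer adapter suffixes win when
several would match, which makes the reported truncation length the
maximal consistent one.

After extraction, reads are cropped to 75 bp and pairs in which either
mate is ≤ 25 bp are dropped (strict inequality: a 26-bp mate survives,
a 25-bp mate does not).

# Strand-invasion detection

For each aligned UMI read the 20-bp genomic context adjacent to the read
start is extracted in the read's orientation: `genome[start−20, start)`
on `+`, reverse complement of `genome[end, end+20)` on `−`; reads whose
window runs off a contig edge are dropped and counted. PCR duplicates are
collapsed on the key (UMI, chromosome, 5′ coordinate, strand, upstream
sequence); the first-encountered record is the survivor, a tie-break that
cannot affect any statistic because only keys are counted. Strand is part
of the key even though position alone might seem enough: opposite-strand
reads at one coordinate have different adjacent sequences, so the
distinction is implied and made explicit.

The match statistic at mismatch level *m* ∈ {0..3} uses the query
`suffix(UMI, 8−m) + motif`, with motif ∈ {∅, `GGG`, `spacer+GGG`}, and
declares a hit when the query occurs **anywhere** within the 20-bp
window. Forgiveness is strictly 5′-consecutive — internal mismatches are
never forgiven. An adjacency-only variant (query must end at the read
start) is available behind the `adjacent_only` flag for sensitivity
analysis; the windowed form is the default because a window-wide search
is what gives the 20-bp parameter meaning. The analytic chance-match
probability for a length-*q* query in a length-*w* i.i.d. uniform window
is approximated as `1 − (1 − 4^−q)^(w−q+1)`; the independence assumption
across offsets is inexact but its error is far below the binomial noise
at the problem sizes used.

The production read filter removes reads matching at `m ≤ 1` with no
motif requirement; motif-conditioned filtering exists behind a flag but
is off by default because the no-motif form is the conservative superset.
The filter runs per read, before deduplication and counting.

# The simulator

`sim_config()` fixes the study conditions; `simulate_dataset()` is
deterministic given the seed and produces genome, annotation, FASTQ,
alignments (the simulator is its own aligner), an exome-style VCF and
truth tables.

* **Genome and genes.** Uniform random contigs; single-interval gene
  models on random strands, laid out with gaps. The analyses in scope
  need feature intervals, not splicing realism; intergenic gaps provide
  background space and `type = "intron"` annotation rows are honoured by
  the feature assigner where a user supplies them.
* **Reads.** Each molecule draws a class (UMI / internal / background),
  a gene and a fragment; mate 1 is the 5′-end cDNA, mate 2 the opposite
  fragment end. UMI molecules carry the full motif; with probability
  `p_tso_tagmentation` the motif moves to mate 2 behind a truncated
  adapter whose suffix length is drawn from
  `adapter_truncation_weights` (default: 2/3/4 nt, equal weight — the
  empirical truncation distribution is unpublished, so this is a
  stand-in, not a claim). `duplicate_factor` emits exact PCR copies of
  each molecule; substitution errors are then drawn independently per
  copy at `error_rate` (default 0.001/base, an Illumina-like scale).
* **UMIs** are sampled *without replacement* within each (cell, gene), a
  generative choice that makes the planted per-gene molecule number an
  exact ground truth for unique-UMI counting (i.i.d. sampling would
  confound counting accuracy with birthday collisions at a rate of about
  `M²/2·4^−8` per gene).
* **Strand invasion.** An invasion read's UMI is copied from the genome
  adjacent to the read start. With configurable weights the upstream
  layout is `…[UMI]·read-start` (UMI immediately adjacent), or
  `…[UMI][GGG]·read-start`, or `…[UMI][spacer][GGG]·read-start` — the
  motif variants place the guanosine tract *between* the UMI-matching
  segment and the read start, where the annealed TSO 3′ end sits, which
  is what makes the motif-conditioned queries (`UMI-suffix` followed by
  the motif) matchable. The motif bases are written into the genome
  before any sequence is extracted, so alignments, upstream windows and
  reads stay mutually consistent.
* **SNPs.** Heterozygous SNVs are planted at gene-interior positions;
  each cell is a carrier with probability `p_carrier` and a carrier
  molecule draws the alt allele with probability 0.5 (both mates and all
  PCR copies of a molecule share the allele). The exome VCF contains the
  planted sites with hard-filter-passing annotations plus decoy records
  that fail the filters and are never planted in reads.

What the simulator does **not** emulate: splicing and isoforms, indels,
quality-score structure, GC/positional coverage bias, chimeras, doublets
and ambient RNA. Passing tests therefore demonstrate the correctness of
the algorithms under their stated models, not robustness to every
artifact of real libraries.

# Counting and diagnostics

Gene assignment is featureCounts-style: a read joins a gene when ≥ 25%
of its aligned length overlaps the gene's exonic intervals; reads
reaching the threshold for several genes are discarded as ambiguous. UMI
reads are assigned stranded, internal reads unstranded.

`unique` counting is the number of distinct UMIs per (gene, cell).
`directional` counting re-implements the network-adjacency collapse —
an edge a→b when Hamming(a,b) = 1 and `count(a) ≥ 2·count(b) − 1`,
components counted after breadth-first traversal from nodes in
descending count (ties broken lexicographically, making the result
order-invariant).

The edit-distance diagnostic compares within-gene pairwise Levenshtein
distances of deduplicated UMIs with a null built by drawing
size-matched sets from the pooled UMI collection. The comparison test is
a two-sided Wilcoxon rank-sum (the raw distance vectors are always
returned so any alternative can be applied); Hamming distance is offered
as a flag since UMIs are fixed-length. When a `cell` column is present,
pooling respects cells; otherwise cells are pooled — both modes exist
because per-cell versus pooled comparison is a user-level choice.

# SNP benchmarking

Exome hard filters are strict inequalities: QD > 2, FS < 60, SOR < 3,
MQ > 40, MQRankSum > −12.5, ReadPosRankSum > −8; a missing annotation
passes by default (configurable). Indels are excluded on both sides and
multi-allelic records are decomposed before comparison. The per-cell
reference list is the exome SNPs covered by **more than 2** of the
cell's reads. Cell calls are restricted to the capture intervals and
non-mitochondrial contigs; TP requires DP > 2 and a reference-list match
by (chromosome, position, alt) — allele-aware by default, with
position-only matching behind a flag; FN = reference − TP; FP = the
remaining DP > 2 calls; TP and FP are re-tallied at QUAL > 20, so the
identity TP + FN = |reference| holds exactly by construction.

For end-to-end runs on synthetic data a minimal pileup caller is
provided (≥ 2 alt reads, alt fraction ≥ 0.2, QUAL = Phred of a binomial
error test at the site depth). It is a deliberately simple instrument:
at het sites with coverage just above the reference-list cutoff it can
miss the alt allele (with coverage 3 the alt is seen ≥ 2 times only half
the time), so caller-based recovery sits below the classification-only
ceiling. Benchmarks of the *classification logic* therefore use
truth-derived calls (`truth_calls_for_cell()`), which score 100% TP with
zero FP on error-free data; the caller is exercised separately.

# Sensitivity statistics

Gene detection uses strict thresholds (count > 0, count > 5).
Saturation curves resample reads without replacement per cell at each
depth. Gene diversity resamples 10 cells per type 100 times and counts
genes detected in **strictly more than** `min_cells = 2` of the sampled
cells; the strict reading is the default and the boundary is
configurable, since "supported by at least two" is a defensible
alternative. Cell-to-cell correlation is Kendall's tau-b (tie-corrected,
via `stats::cor`, oracle-checked against an O(n²) enumeration in the
tests) on genes expressed in all compared units — per-pair shared genes
in pairwise mode, group-aggregate support when groups are given.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally, converted at the SAM and
  VCF boundaries.
* Empty inputs yield empty, typed results: an empty invasion report
  flags percentages as absent (`NA`), not zero; a diagnostic without a
  two-UMI gene reports `computable = FALSE`.
* Downsampling clamps (`n ≥ available` returns the input unchanged) and
  preserves input order.
* All randomized entry points accept a seed and are bit-reproducible
  given it.

# Problem sizes

The test-suite and acceptance-script simulations use 50,000 UMI reads
for invasion-rate recovery and null calibration (binomial 3-s.d. bands
around the planted rate plus the analytic null), 100,000 pairs for the
R2-rescue rate, 20 replicates of small single-cell datasets for the
unique-vs-directional comparison under a 0.005 error rate, and 3 cells ×
50 planted SNPs for the benchmark identities. These sizes put the Monte
Carlo noise of every checked quantity well inside its tolerance while
keeping a full run in minutes on one core.

# Known limitations

* The invasion statistics assume substitution-only sequencing errors;
  indel errors would shift the upstream window.
* The analytic null treats window offsets as independent; exact
  occurrence probabilities differ at the fourth decimal of a percent.
* The pileup caller is not a production variant caller and should not be
  used on real data; real VCFs are accepted directly.
* Gene models are single-interval; spliced alignments (N CIGAR
  operations) are measured by reference span in overlap computations.
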