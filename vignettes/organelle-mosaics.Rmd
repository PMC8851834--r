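---
title: "Dissecting organelle genome mosaics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting organelle genome mosaics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orgamosaic)
```

## The problem

Plant organelle genomes are mosaics. A mitogenome accumulates copies of its
own plastome (MTPT), dispersed repeats, and — especially in parasitic plants
such as dodders — foreign DNA acquired horizontally from host lineages.
Layered on top of this, individual genes can suffer structural accidents:
the mitochondrial gene *ccmFc*, canonically two exons split by a group II
cis-splicing intron, can break into fragments that behave as independent
genes, with intronic insertions, shifts from cis- to trans-splicing, and
coding regions that expand to the nearest usable stop or start codon.

`orgamosaic` implements the comparative analyses this situation calls for:

1. **partition** of a focal mitogenome into five homology classes,
2. **donor attribution** of specific sequences and cross-genome coverage
   matrices for HGT-like candidates,
3. **fragment-anchor synteny** between genome pairs,
4. **quadripartite/IR detection** in plastomes, and
5. **gene-fission analysis** (breakpoints, insertions, expansions, splicing
   evidence, binding-region integrity).

Everything runs on tibbles: genome sets are one row per sequence, and every
analysis returns a tibble or an object with `tidy()`/`glance()` methods.

## The homology engine

All analyses reduce to local nucleotide homology. The engine seeds on exact
`word_size`-mers (default 16) on both strands, extends each seed without
gaps under an x-drop rule, and then chains co-linear HSPs within a diagonal
band using affine gap costs (a gap of length *g* costs
`|gap_open| + g|gap_extend|`, defaults 5 + 2g). This chaining step plays the
role of a banded gapped extension: on the genome sizes this package targets
the two are equivalent in effect, and the chained score never exceeds the
optimal local alignment score, which the test suite verifies against a full
Smith–Waterman oracle (`sw_oracle()`, computed independently via
`Biostrings::pairwiseAlignment`).

E-values use Karlin–Altschul statistics with the ungapped nucleotide
constants K = 0.71, lambda = 1.37 applied to gapped scores. This is an
approximation; all downstream logic depends only on the e-value *ceiling*
(default 1e-5), not on exact BLAST agreement, and all identity thresholds
operate on percent identity, which the engine computes exactly. N never
matches anything, never seeds, and never counts toward identity numerators.

Circular genomes are searched through the doubled-sequence device: the
subject is concatenated with itself, hits are deduplicated back to the
original frame, and a hit crossing the origin is reported modularly
(`s_end < s_start`). The IR detector additionally scans a half-rotated copy
of the circle because the query side of a self-search is linear.

Determinism matters for reproducible pipelines: ties are broken by bitscore,
then alignment length, then subject id, then subject start, and identical
inputs yield byte-identical hit tables.

## The five-class partition

`classify_genome()` labels every base of a focal mitogenome:

| class | rule | threshold |
|---|---|---|
| PLASTID_LIKE | hit against any supplied plastome | identity > 90% |
| REPETITIVE | self-hit | identity > 95% |
| CONSERVED | qualifying hit in *all* other family mitogenomes | e-value ≤ 1e-5 |
| SPECIFIC | no hit against any other-genus mitogenome | e-value ≤ 1e-5 |
| OTHER | everything else | — |

Classes overlap, so bases are assigned by fixed precedence
PLASTID_LIKE > REPETITIVE > CONSERVED > SPECIFIC > OTHER. Precedence is a
design choice the underlying stacked-bar representation leaves open; we put
plastid-like first because those bases have a known non-mitochondrial origin
regardless of what else they resemble. A consequence worth noting is that
computing specific sequences before or after masking plastid-like and
repetitive bases yields the same final segments — the precedence cascade *is*
the masking — so no separate ordering switch is needed.

"All family members" is interpreted at species level by default
(`conserved_scope = "species"`); a genus-level mode requires a homolog in at
least one member of every other genus. Segments are reported at 1 bp
resolution (no smoothing); a `min_segment` merge option exists but defaults
off, keeping the core definition pure. Circular focal genomes are linearised
at offset 0 for reporting.

Two monotonicity properties follow from the definitions and are enforced in
tests: raising the plastid identity floor never increases plastid-like bp,
and adding a genome to the family never increases conserved or specific bp.

## Donor attribution and coverage matrices

Specific (GSS) segments are attributed by their single best hit over a donor
pool in which each record carries a taxonomic order label — a stand-in for a
broad nucleotide-database search that keeps the analysis self-contained and
testable. Best hits shorter than 100 bp are treated as no hit ("unknown");
orders are aggregated by summed length, with a >5 kb rule marking the
display subset. Segments whose best hit exceeds 500 bp are the HGT-like
candidates; their per-base union coverage against each relative genome forms
the coverage matrix (entries in [0, 1] by construction — summed hit lengths
could exceed 1, union coverage cannot). An order-level mean summariser is
provided for the aggregated view.

## Synteny by 50-bp fragments

Whole-mitogenome synteny uses the fragment device: each genome is cut into
consecutive 50-bp windows that act as pseudo-genes. Each fragment of A is
searched against B in full (not exact-matched), so diverged genomes still
anchor; an anchor requires identity ≥ 90% over ≥ 80% of the fragment. The
fragment searches use a 12-mer seed rather than the global 16: at a few
percent pairwise divergence a 50-mer often lacks a clean 16-mer run, and a
shorter seed keeps sensitivity at fragment scale without affecting
genome-scale searches. Chaining is a native repeated weighted
longest-increasing/decreasing-subsequence with a 10-fragment gap cap and a
5-anchor block minimum; anchors are also exported in the three-column
`.anchors` text format so collinearity can be cross-checked with external
tools.

## IR detection

`detect_ir()` finds the maximal near-identical (≥ 99.9%) inverted pair at
least 1 kb long, derives the two single-copy regions between the copies on
the circle, names the longer LSC, and rotates coordinates so LSC starts
at 0. The 99.9% tolerance reflects that plastome IRs are rarely perfectly
identical; the reported boundary is the end of the maximal extension. A
circle with no qualifying pair returns `NULL` — the IR-loss situation of
dodder plastomes — and region lengths are invariant under rotation of the
input, which the tests assert directly. `junction_report()` then places gene
models relative to the four junctions, flagging IR-internal genes with their
mirrored duplicates.

## Fission analysis

The fission analyser works in *reference region* coordinates: the span of
the intact two-exon reference gene, oriented 5'→3'. Fragments located in a
target are labelled FR1, FR2, ... by reference order. The measurements are:

* **break 1** — the exonic reference span between FR1 and FR2, in nt and aa
  (floor of nt/3 in the reference frame), echoed as reference codon
  coordinates. Micro-homology at junctions resolves leftmost; fragment
  overlaps beyond the seed word size raise a consistency error.
* **break 2** — the intron-side gap between FR2 and FR3, in nt (0 for a
  clean split).
* **FR2–FR3 gap** — adjacent (same locus, same orientation, ordered, within
  `max_insertion` = 10 kb) with an insertion length and plastid-derived
  content (the >90% plastome rule applied to the gap sequence), or
  separated. The 10 kb cap operationalises "same locus" on single-sequence
  assemblies: published intronic insertions are a few kb, while relocated
  fragments sit tens of kb apart or on different contigs.
* **expansions** — downstream in-frame stop scan for the first gene
  (codons gained, stop exclusive) and upstream nearest in-frame ATG scan for
  the second (ATG inclusive, no intervening stop), each within a 3,000 nt
  window; an exhausted window sets an unresolved flag. A premature stop is
  reported as a truncation when the expansion seen in non-truncated
  relatives (`full_expansion_aa`) is supplied — with a single genome there
  is no way to distinguish a short expansion from a truncated long one, so
  the comparison baseline is explicit rather than guessed.
* **binding region** — the reference intron window (the ~48-nt segment
  recognised by the nuclear splicing factor WTF9) re-located in the target:
  full-length indel-free match = preserved; otherwise the insertion length
  interrupting it is reported, NA when the window is absent.
* **splicing call** — from per-base transcriptome depth: E = median over
  FR2/FR3 exonic bases, I = median over the window immediately downstream
  of FR2 (the region that would connect FR2 to FR3 in a cis-spliced
  precursor). The call is trans when I < 50 and E > 400 (the low/high
  coverage bands), cis when I ≥ 0.5 E, ambiguous otherwise — and ambiguous
  whenever E ≤ 50, since below the low band there is no signal to compare.
  The 50/400 bands are conventional display thresholds for this kind of
  evidence; the 0.5 cis ratio and the low-signal guard are this package's
  codification of a qualitative argument, and all three are configurable.

Translation uses the standard genetic code (plant mitochondria use the
universal code). RNA editing is not modelled: for expansion scans this is
safe — edited sites are absent from newly expanded regions — but
`classify_gene_status()` calls on heavily edited genes should be read with
that limitation in mind. Gene status follows the pseudogene convention:
premature internal stop, non-triplet length change, or truncation beyond
20% of the reference protein.

## The synthetic-data generator

Because real organelle assemblies are too large for unit-scale validation,
every analysis is exercised on generated genomes with planted truth.

`simulate_family()` builds a family (default 3 genera × 2 species) from one
ancestral core (default 50 kb — large enough that seed statistics and
e-values behave as at genome scale, small enough that a full partition runs
in ~2 s) with per-genome substitutions (2%, a typical congeneric mitogenome
divergence) and rare short indels (5×10⁻⁴). Planted per genome: two plastome
copies (3 + 2 kb at 99% identity), a three-copy 800 bp repeat family, a
genus-shared 3 kb segment, donor-derived species-specific segments
(2.5 + 2 kb, verbatim, with order labels), and a 2 kb block shared by all
but one genome — bases that are neither conserved-in-all nor specific, the
"other" class. The truth table records every interval with its class.

`simulate_fission_fixture()` plants the published *ccmFc* layout at absolute
scale: FR1 = 163 codons of exon1, a 129 nt (43 aa) deletion at reference
codons 164–206, a clean intron split, a 3,500 bp insertion containing a
2,800 bp plastome copy (1,300 bp in the epilinum layout; relocated fragments
in the grammica layout), a 48-nt binding window (28 bp insertion in the
americana layout), an engineered stop 185 codons downstream of FR1 and an
ATG 118 codons upstream of FR2, and an optional nonsense codon 10 codons
into the expansion. One construction detail matters: every junction between
a planted fragment and its new context is built from bases that mismatch
the reference continuation. Without this, chance matches at a junction
create genuine micro-homology — the planted breakpoint itself becomes
ambiguous by a base or two, and no aligner could recover the stated numbers
exactly. The guard makes the planted truth well-defined; it is a property of
the fixture, not of the analysis. The same guard protects the planted IR
boundaries in `simulate_plastome()`.

`simulate_coverage()` draws Poisson depth: expressed intervals at the base
depth (default 500), the FR2–FR3 connecting region at mean 10 (trans-like,
separately transcribed precursors) or 0.8 × base depth (cis-like), and
background at mean 2.

What the generator does *not* emulate — and hence what green tests do not
show about real data: recombination-driven structural heterogeneity and
substoichiometric isoforms, transition/transversion bias (irrelevant to
identity-threshold logic), sequencing error, fragmented or misassembled
inputs, and genuine nt-scale donor databases. Attribution accuracy on real
data is bounded by donor-pool completeness, which here is planted.

## Numerical and degenerate-input conventions

Internal coordinates are 0-based half-open everywhere; on-disk formats use
their own conventions (GFF3 and the 12-column hit dialect 1-based inclusive,
BED 0-based half-open). Empty inputs produce empty tibbles or files, not
errors, except where an analysis is undefined (no plastomes for the
plastid rule, a donor pool with no records, fewer than two family members
for conservation). A gene absent from a target is a zero-row fragment
table, not an error. Proportions sum to 1 within 1e-9 and segment tables
always tile `[0, len)` exactly; both are asserted on every partition in the
test suite.

## Problem sizes

The shipped test and acceptance runs use 50 kb cores (families of six),
36 kb plastomes, ~10–35 kb fission targets, and 20 seeded replicates for the
recovery study — sizes chosen so the definitions are exercised at realistic
sequence-statistics scale while a full run stays in the minutes range on a
single core.
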