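---
title: "Comparative centromere genomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative centromere genomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrosynteny)
```

This vignette documents the models behind each analysis step, the
parameters that matter, what the synthetic-data generators do and do not
emulate, and the design choices made where several constructions were
defensible.

## The comparative setting

Two related genomes can organise their centromeres in radically
different ways: a handful of multi-megabase satellite-based
monocentromeres in one species versus dozens of small CENH3-positive
centromere units distributed along holocentric chromosomes in a sister
species. If the two genomes are otherwise largely syntenic, the gene
order around each centromere becomes an instrument: a centromere
interval whose flanking genes sit inside one conserved syntenic block
of the other genome, where that other genome has no centromere, must
have arisen de novo after the species diverged. The package implements
this argument end to end, together with the satellite-array and
ChIP-enrichment analyses that characterise the centromeric sequence
itself.

## Ortholog links

Classification follows a strict three-step recipe. First, protein
alignment hits below 90% identity or 150 aligned amino acids are
discarded; both thresholds are *keep-if-equal* ("below" is removed, the
boundary passes) and are exposed as `filter_thresholds()`. Second,
multiple HSPs between the same gene pair are one similarity
relationship: only the best-scoring hit (bitscore, then identity, then
smallest subject id) is kept. Third, a gene qualifies as conserved
single-copy when its similarity is to a *single* gene of the other
genome. The default `reciprocal` mode additionally requires the
converse, which makes the pair set symmetric in the two genomes; the
literal one-direction variant is retained as `mode = "one_way"`, where
we additionally drop any subject gene claimed by two different query
genes so that the output never repeats a gene on either side.
Self-hits and hits naming unknown proteins are ignored or rejected
according to `on_unknown`.

Uniqueness is deliberately counted *after* noise filtering: a gene with
one strong hit and three sub-threshold ones is single-copy. The same
ordering is used by the alignment-based ortholog pipelines this module
mirrors.

## Synteny blocks and rearrangements

No blocking algorithm is canonical at this scale, so the package uses
greedy rank chaining, fully parameterised and oracle-testable:

* links are ranked per chromosome on each genome by position;
* within each chromosome pair, a link extends the open chain iff it
  steps in the chain's genome-B direction and the rank gap is at most
  `max_gap_genes` (default 10) on both genomes;
* chains shorter than `min_block_links` (default 5) become unchained
  leftovers.

Two refinements matter in practice. Chaining *per chromosome pair*
(rather than one pass over the genome-A order) makes the result
invariant under swapping the two genomes: links of other pairs that
interleave on either genome are invisible to a pair's chains. And a
boundary-refinement pass reassigns a chain's last link to the following
chain when it fits there with a strictly smaller genome-B rank step;
without it, the first link of an orientation-reversed run is absorbed
by the preceding collinear chain (the direction-setting step is a large
rank jump), which would shrink every inversion block by one link.

An **inversion** is a block on the minority orientation of its
chromosome pair, with at least `min_event_links` (default 5) links; a
chromosome pair that is entirely reversed is its own dominant context
and yields no calls. A **translocation** is a block whose chromosome
pair disagrees with the dominant partnering of either of its
chromosomes; adjacent calls on the same pair within `merge_gap_ranks`
are merged, so a single moved segment split by chaining still counts
once. Exact 50/50 ties in a dominant context resolve deterministically
(+1 orientation, lexicographically smallest chromosome) with a warning.

## Centromere-origin classification

`project_interval()` takes the nearest link entirely left and right of
an interval; when both exist on one partner chromosome, the projection
spans the region between their gene-proximal edges — conservative inner
bounds, robust to the flank genes' own lengths. A genome-B unit is

* `corresponding` when its projection overlaps a genome-A unit by at
  least `min_overlap_frac` (default 0.1) of the smaller interval — a
  deliberately permissive knob, since the biological claim being tested
  is qualitative (positions "mostly do not correspond");
* `de_novo_insertion` when the projection resolves, overlaps no unit,
  and the flanks belong to one block or to two blocks that continue
  each other (same pair, same orientation) — the unit splits a
  conserved syntenic run;
* `unresolved` otherwise (missing flank, discordant partner
  chromosomes, terminal units).

## Satellite analysis

**Dyads.** `find_dyads()` reports all maximal inverted repeats with arm
length ≥ `min_arm` (default 4), loop ≤ `max_loop` (default 12) and up
to `max_mismatch` arm mismatches (default 0); candidates whose arms are
both contained in another reported dyad are suppressed, and `N` never
pairs. The unit tests hold the implementation equal to an exhaustive
enumeration over all (arm1, arm2, length) triples.

**Hairpin score.** No thermodynamic folder is used (none is claimed to
be equivalent): the score `3·GC + 2·AT − 0.5·max(0, loop − 3)` over
perfect-pairing stems is a transparent proxy for stem-loop potential,
again verified against brute force.

**Monomer tiling.** `decompose_array()` is a greedy scan: at each
position the consensus and its reverse complement are compared with
candidate windows of the monomer length ± 20% by edit distance, and the
best orientation is accepted at ≥ `min_identity`, else the scan
advances one base. The default floor of 70% sits below the identity
band of diverged monomer variants (~80–90% for variants up to ~15%
total divergence) but above the ~60% edit identity of unrelated DNA, so
variant copies tile while flanking sequence does not. Greedy tiling is
not an optimal segmentation; on mutation-free input it is exact
(coverage and identity 100%), which the tests assert.

**HOR period.** For monomers in array order, mean pairwise identity is
computed at lags 1..20. In a period-p array, identities at lags that
are multiples of p form a high band (within-variant) and all other lags
a low band (between-variant). Each candidate period is therefore scored
by the *contrast* between the mean identity at its multiples and at all
remaining lags; the contrast is maximal at the true period (for a
multiple 2p, the complement still contains the high lags p, 3p, …,
raising its baseline). A period must reach a contrast of `margin`
(default 2 percentage points — lag means average dozens of monomer
pairs, so their sampling noise is a few tenths of a point) and a
multiple-lag identity of `min_hor_identity` (default 88%, separating
the bands up to ~6% per-copy divergence). An earlier rule — smallest
lag exceeding the lag-1 identity by a fixed margin — misidentified
periods whenever the between-variant band fluctuated toward the
within-variant band, which is why the contrast form is used. With
uniformly high identity at all lags the array is a plain tandem
(period 1); with no band reaching the floor there is no periodic
structure (`NA`).

## ChIP enrichment

Cluster enrichment and the windowed track share one formula: the ratio
of pseudocounted read proportions,
`((chip + p)/chip_total) / ((input + p)/input_total)`, reported as-is
per cluster and as log2 per window (1-kb windows by default). The
pseudocount (default 1 read) keeps zero-input windows defined; the
choice is not critical since it cancels at moderate depth. Both
statistics are invariant under rescaling both library totals, and the
track is antisymmetric under swapping ChIP and input — the tests check
both identities. `call_enriched_segments()` extracts maximal runs of
windows at or above a log2 threshold, bridging sub-threshold gaps up to
`merge_gap` windows and dropping runs shorter than `min_len`. It stands
in for model-based broad-peak calling, deliberately: on the planted
blocks the package simulates, run extraction recovers boundaries to
within a couple of windows, and its simplicity makes it exactly
testable (idempotence on its own indicator track).

Cross-species spike-in chromatin mixing and read alignment are upstream
of this module: counts are consumed as given, with no multi-mapping
logic.

## What the generators emulate — and what they do not

`simulate_genome_pair()` plants, in rank space, non-overlapping
inversions (gene order reversed, strands flipped), translocations
(a gene run moved to another chromosome, each with a distinct
source–destination pair so merged calls stay distinct), gene-free
centromere insertions, and duplicate gene copies; genome-B coordinates
are re-laid on a uniform grid (1 gene per 10 kb) with insertions
shifting downstream genes. Proteins mutate to an *exact* target
identity (positions sampled without replacement), and alignment hits
are emitted directly from the truth, plus sub-threshold noise hits that
exercise the filter. Centromere insertions are restricted to gaps whose
surrounding genes are untouched, consecutive in the ancestral order,
and part of a run of at least 6 such genes — the de novo scenario the
classifier is designed for is precisely a unit splitting a conserved
block, and shorter runs cannot form a block at the default
`min_block_links`. The genome-A centromere region (one interval on
chromosome 1, mid-chromosome) is likewise kept clear of planted events.

Satellite variants carry an exact substitution count
(`variant_divergence`, default 0.08 of the monomer, i.e. between-variant
identities near 85%), so the planted HOR contrast is guaranteed rather
than merely expected; per-copy mutation is then applied at the
configured rate, and orientation flips reverse-complement whole runs of
copies. ChIP counts are Poisson with a constant fold enrichment inside
the planted blocks.

None of this emulates real data's indels, segmental duplications,
tandem gene families, transposon insertions in arrays, GC-coverage
bias, or mapping artefacts. Passing the planted-truth tests therefore
shows that the algorithms are correct under their stated models — not
that the thresholds are optimal for any particular real genome pair;
the thresholds exist as parameters for exactly that reason.

## Numerical choices and problem sizes

* Coordinates: GFF3 gene models stay 1-based inclusive; every other
  interval is 0-based half-open; converters sit at module boundaries.
* Representative transcript: longest summed CDS, ties to the smallest
  transcript id.
* Edit distances use the C-level Levenshtein in base R; candidate
  windows are restricted to the monomer length ± 20%, which bounds the
  work per accepted monomer. Monomer series longer than 200 copies are
  truncated for HOR detection.
* Mb-per-chromosome summaries round half-up to one decimal, the
  precision genome reports print.
* Rearrangement and centromere-origin recovery is exercised on genome
  pairs of 4 chromosomes × 60 genes across 20 seeds; dyad and
  longest-common-substring implementations are held equal to brute
  force on 500 random cases each (n ≤ 80 and ≤ 100); HOR recovery uses
  100 arrays of 100 monomers at 5% per-base mutation. These sizes make
  every oracle exhaustive while the full suite stays fast.

## Known limitations

Rearrangement typing is deliberately coarse: nested or overlapping
events, fissions/fusions and breakpoint-resolution calls are out of
scope, as are orthogroup inference for multi-copy families, thermodynamic
folding, repeat discovery, and read-level processing. Projection
resolves only between flanks on one partner chromosome; units at
chromosome ends remain `unresolved` by construction.
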