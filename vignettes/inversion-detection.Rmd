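---
title: "Comparative and genetic detection of a chromosomal inversion"
author: "invscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative and genetic detection of a chromosomal inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invscan)
```

## The problem

A disease-resistance locus introgressed from a wild relative into a crop
often refuses to be fine-mapped: recombination in the region collapses in
crosses between the crop and the wild donor. One classic cause is a
chromosomal inversion — the introgressed segment is reversed relative to
the crop genome, and crossovers inside an inversion heterozygote produce
inviable unbalanced gametes. Establishing the inversion requires several
independent lines of evidence, because each one alone is fragile: a draft
assembly of the wild genome can be mis-joined; marker orders inferred from
one cross can be confounded by genotyping error; repeat families (in
resistance-gene clusters, typically NB-LRR genes) sit exactly at the
breakpoints and blur alignment-based views.

`invscan` implements that chain of evidence as testable code: comparative
anchoring of a draft assembly to the reference region, reference-guided
superscaffolding, crossover-parsimony marker ordering, simulation-backed
suppression tests, breakpoint localization from a BAC-like clone of the
introgression line, and in-silico PCR for breakpoint-diagnostic primer
pairs. A synthetic-data generator produces the whole study system with
known ground truth, so every stage is scored against the planted signal.

## Anchoring and synteny model

Two sequences are compared through exact-match seeds: all *k*-mers (default
*k* = 21) whose *canonical* form — the lexicographic minimum of the
*k*-mer and its reverse complement — occurs at most `max_occurrences`
times (default 1) in *each* sequence. Seeds on one diagonal are merged
into maximal anchors; a minus-strand anchor means the query segment equals
the reverse complement of the target segment. Two properties motivate the
canonical-uniqueness rule:

* chance 21-mer collisions are negligible at region scale (4^21 ≈ 4.4e12),
  so every anchor is near-certain evidence of homology;
* an inverted repeat cassette — the model's stand-in for the NB-LRR pair
  that flanks real inversion breakpoints — contains *k*-mers whose
  canonical form occurs twice (once per copy, once forward and once
  reverse-complemented), so cassette *k*-mers are dropped automatically
  and breakpoint intervals come out anchor-free, mirroring how such
  repeats align ambiguously in both orientations in real data.

*k*-mers containing `N` are skipped rather than treated as wildcards: an
assembly gap is absence of evidence. *k* is capped at 25 so the base-4
integer encoding stays exact in double precision.

Chaining is greedy in target order within each strand: a chain breaks when
the inter-anchor target gap exceeds `max_gap` (default 20 kb, generous
against N-runs and cassette insertions), when the diagonal drifts by more
than `max_diag_drift` (default 1 kb, absorbing indel divergence), or when
query order stops being monotone. A full dynamic-programming chainer adds
nothing at ≤ few-Mb regional scale with near-unique anchors. Blocks with
fewer than `min_block_anchors` (default 3) anchors are discarded as noise.

An **inversion call** is a maximal run of minus-strand blocks flanked on
both sides by plus-strand blocks or a sequence end, with target span at
least `min_size` (default 10 kb — large enough to ignore local hairpin
artefacts, small relative to the ~200-kb signal of interest). Nested
orientation structure inside a minus run is not separately called; the
call reports the outer interval and the two anchor-free breakpoint
intervals. Boundaries are accurate to about `cassette_len + k` — the
cassettes are unanchorable, so that slack is intrinsic, not a tuning
choice. Breakpoints are always reported as intervals, never single bases:
the data cannot resolve a breakpoint more finely than the anchors allow.

All coordinates in this package are 1-based and closed, the
Biostrings/IRanges convention; BED output is 0-based half-open and says so
in a header line. (An internal 0-based half-open convention was
considered and rejected: every dependency used here is 1-based, and one
convention with explicit conversion at the BED boundary leaves fewer
places for off-by-one errors.)

## Scaffold placement and superscaffolding

Each draft scaffold is anchored to the reference with the same machinery
(but `min_block_anchors = 1`, since a perfectly matching scaffold yields a
single long anchor). Its placement is the *hull* of all its chained
blocks, extended by *projecting the unanchored scaffold tails* onto the
target: terminal anchors start wherever the first divergence-free *k*-mer
happens to sit, and without projection that trimming biases every gap
estimate by tens of bases. Orientation is decided by majority anchor
coverage; a scaffold spanning an inversion breakpoint legitimately chains
in both orientations, and the minority coverage is reported rather than
hidden (`minority_coverage_bp`), since for such a scaffold "orientation"
is genuinely ambiguous.

Gaps between consecutive placements are estimated by reference projection
(`max(0, next_start - this_end - 1)`, overlaps clamped to zero and
flagged). The estimate inherits error from indel divergence inside the
gap; with the defaults this is a few bases on a 606-bp or 4.3-kb gap. The
superscaffold concatenates oriented scaffolds with N-runs of the
estimated sizes (minimum one N, so component boundaries stay visible) and
is described by AGP v2.0 rows, the community format for scaffold
composition.

## Crossover parsimony on phase-unknown genotypes

F2 genotypes are coded `A` (homozygous first parent), `B` (homozygous
other parent), `H` (heterozygous), `AH` (dominant assay: A or H, never
B), `-` (missing). An individual's two haplotypes across *m* ordered
markers form a path through four phase states (aa, ab, ba, bb); each code
constrains the state set at its marker, and the cost of an adjacent-state
transition is the number of haplotype positions that switch. The minimum
total cost over all consistent paths — computed exactly by dynamic
programming, verified against exhaustive enumeration of all 4^6 paths for
all 5^6 length-6 code vectors — is the minimum number of meiotic
crossovers needed to explain the genotypes under that marker order.
Because `AH` and `-` relax toward the cheapest resolution, ambiguous calls
never manufacture recombinants (the conservative reading of dominant CAPS
scores).

Candidate orders are the reference order plus every contiguous-segment
reversal — the inversion hypothesis class — with optional exhaustive
search for ≤ 7 markers; full permutation search is out of scope.
Ties break deterministically: reference order first, then smaller
reversed segment, then lexicographic. The diagnostic contrast is the
worked example in the README: `[A,H,A,H,H,H]` costs 3 crossovers as
given and 1 after swapping the two inversion markers, so a single
plausible recombinant replaces an implausible triple crossover.

Two-point analysis defines a *recombinant individual* by a forced
(minimum ≥ 1) pairwise crossover count; the per-gamete recombination
fraction is total minimum crossovers over 2 × informative individuals,
converted to map distance by the Haldane inverse `-50 ln(1 - 2r)`.
Haldane (not Kosambi) is used throughout because the simulator is
interference-free; the estimator slightly underestimates large distances
(opposite-phase double recombinants in an H/H pair resolve to zero), a
bias that is O(r²) and irrelevant at the few-cM scale where it is used —
the calibration test shows a mean within ±1 cM at 4.5 cM.

Suppression detection asks whether observing zero recombinants is
surprising: with expected map distance `d` (from a genome-wide cM/Mb rate
times the physical distance, or supplied directly from a reference
genetic map), Haldane gives `r`, and the pair is flagged iff zero
recombinants were seen while `(1 - r)^(2n) < alpha`. Three recombinants
among 88 individuals never flag, regardless of expectation.

## The meiosis simulator

Crossovers per inter-marker interval are Poisson(d_cM/100) per gamete, no
interference; a gamete switches parental haplotype where the count is
odd. Generations beyond F2 are produced by selfing every individual once
per generation with independent meioses. Suppression is *absolute*: when
the cross is segregating for the inversion (`inversion_het = TRUE`), any
meiosis whose parent carries two different haplotypes inside a
suppression interval contributes zero crossovers there — the crossover
products are inviable, so none are observed. An inductive consequence
(tested as a hard invariant) is that no gamete ever shows an allele
switch inside a suppressed interval, across all generations: in
homozygotes a crossover is allowed but genotypically invisible. A
`halo_cM` parameter (default 0) widens each suppressed interval, because
in real data the suppressed block can extend beyond the physical
inversion; no value is asserted since the data to calibrate it do not
exist at desk scale.

Dominant markers collapse {A, H} to `AH` at scoring time only; the
underlying haplotypes are unaffected. F2 transmission is two independent
gametes per individual — no segregation distortion, no selfing bias.

## Breakpoints and in-silico PCR

A BAC-like query is chained against the reference along the *query* axis;
every adjacent block pair that disagrees in strand **or** jumps more than
`jump_threshold` (default 20 kb) on the target is a breakpoint call,
reported as the anchor-free query interval between the blocks. The jump
criterion matters: a breakpoint can bring two distant loci into ~18-kb
proximity without any strand flip.

In-silico PCR finds all annealing sites of both primers on both strands
(exact match by default; with `max_mismatches > 0` the three 3'-terminal
bases must still match exactly, since 3' mismatches abort extension) and
reports every convergent arrangement: `product` within `max_product_len`
(default 5000 bp, the standard-vs-long-PCR boundary), `over_max_len`
beyond it, nothing for divergent or same-orientation site pairs. The
exact-match default keeps tests deterministic, as ordinary PCR primers
are designed to match their template perfectly.

The diagnostic panel uses three pairs designed by `design_primer()`, which
scans candidate windows near a position and *verifies specificity
in-silico* (present/absent in designated templates, both orientations) —
the computational analogue of checking a diagnostic primer against the
genomes at hand, and the reason the panel's presence/absence pattern is
deterministic rather than dependent on where random SNPs happen to fall:

* **junction pair** spanning the introgression junction (forward primer
  from the reference background, absent from the wild genome; reverse
  from the wild-derived side, absent from the reference): product only
  from the introgression line;
* **reference pair** (reverse primer from the reference side of the
  junction, absent from the line): product only from the reference;
* **inversion-flank pair** spanning the inversion breakpoint carried by
  the line, both sites present in the reference where they lie in the
  same orientation: product from the rearranged templates, none from the
  reference — the same-orientation geometry that explains a failed
  amplification in a differently rearranged genome.

## The synthetic study system

The generator plants, in order: substitutions (default 2 %), short indels
(default 1e-4, sizes 1–6, kept clear of the inversion boundaries so
realized breakpoints are well defined), reverse complementation of the
inversion interval (default 300,001–500,000 of a 1-Mb region at GC 0.36),
an inverted cassette pair at the flanks (default 3 kb at 95 % identity),
and optional N-runs. Fragmentation deletes sequence at the cuts (default
606 bp and 4.3 kb — the within-reach gap sizes a draft assembly typically
leaves) and shuffles order and strand, because a draft gives no layout
guarantees. The introgression line substitutes the wild segment
homologous to a reference interval into the reference background. Every
derived object carries a truth ledger (realized coordinates, junctions,
scaffold layout) against which the pipeline is scored.

What the generator does **not** emulate: real NB-LRR gene structure (the
cassettes are arbitrary inverted repeats — sufficient for the repeat
masking they exist to exercise, silent on protein-space homology),
sequencing reads or assembler behaviour beyond fragmentation, segregation
distortion, genotyping error, and crossover interference. Passing tests
therefore demonstrate that the *methods* recover planted structure under
realistic divergence and fragmentation — not that any particular real
genome contains an inversion.

Randomness is controlled by one master seed; per-stage seeds derive from
it by fixed offsets (`derive_seed()`), so stages are reproducible jointly
and in isolation.

## Problem sizes and numerical choices

The test suite and the acceptance script run the boundary-recovery
experiment on twenty 1-Mb pairs (the scale at which a 200-kb inversion
with 3-kb cassettes is a realistic regional comparison) and the scaffold
experiment on twenty 150-kb systems, sizes chosen to keep a full run in
the minutes range on one core while leaving every rate estimable from 20
Bernoulli trials. Degenerate inputs are handled explicitly: zero-length
inversions mean "no inversion"; empty anchor sets chain to empty block
lists and call nothing; a query with no anchors warns and returns an
empty call set; `r >= 0.5` maps to an unbounded (infinite) Haldane
distance rather than NaN.

## Known limitations

* Anchoring is exact-match: divergence above ~5 % thins 21-mer anchors
  severely; the remedy (smaller *k* or inexact seeding) trades away the
  uniqueness guarantees and is out of scope.
* The dominant-orientation rule assigns one orientation to a
  breakpoint-spanning scaffold; the minority chain is logged, not
  resolved — mis-join detection and scaffold breaking are out of scope.
* Gap estimates are reference projections; without reads or PCR there is
  no independent gap measurement.
* The parsimony search covers single contiguous reversals (plus
  exhaustive search for small panels); multiple or nested rearrangements
  need the exhaustive mode or more markers than it supports.
* In-silico PCR is purely positional: no melting temperature, dimers, or
  degenerate bases.
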