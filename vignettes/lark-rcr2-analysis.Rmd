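---
title: "Methods: remnant control regions, tandem repeats and gene orders in lark mitogenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remnant control regions, tandem repeats and gene orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larkCR)
```

## The problem

Most vertebrate mitogenomes carry a single control region (CR), the
non-coding region that regulates replication and transcription. Several
bird lineages instead carry two, the product of a tandem duplication of
the CR and its neighbouring genes followed by loss of the redundant
gene copies (the tandem-duplication–random-loss, TDRL, model). In
larks the second copy has decayed into a *remnant* CR2: none of CR1's
conserved elements (ETAS1–2, the F/E/D/C/b/B boxes, CSB1) remain, and
what is left is a 5′ non-repeat region (5NR), a tandem-repeat array
(TR), and a 3′ non-repeat region (3NR). The questions this package
operationalises are: which duplication histories can produce the lark
gene order; where did the rCR2's sequence come from; and how do the
repeat units within an array originate and evolve (unit haplotypes,
divergent initial units, units formed by fusing two smaller units,
and the stem–loop-forming ability that favours slipped-strand
mispairing).

## Sequence alignment and the identity convention

All pairwise comparisons use an affine-gap Smith–Waterman local
alignment implemented in the package (`local_align()`), with defaults
match +5, mismatch −4, gap opening 10, gap extension 0.5 — the
classical EMBOSS-`water` nucleotide defaults; a gap of length $L$
costs $10 + 0.5L$. Identity is

$$\mathrm{identity} = \frac{\text{identical columns}}{\text{all alignment columns, gap columns included}} \times 100.$$

The denominator choice matters: the minimum similarity among the
full-length *Alaudala cheleensis* haplotypes arises from a 68-column
alignment containing one insertion column (64 identities / 68 columns
= 94.1%); counting only non-gap columns would give 95.5% and no
convention would then reproduce the published per-species ranges.
Co-optimal alignments are resolved deterministically: the end cell
with the smallest row-major $(i, j)$ wins, and traceback prefers
diagonal over vertical over horizontal steps. Scores are
cross-checked in the test suite against an exhaustive enumeration
oracle on short strings and against an independent dynamic-programming
implementation (`Biostrings::pairwiseAlignment`) on the decoded
haplotype pairs.

Repeat-unit haplotypes are stored the way the field prints them: a
consensus row plus dot/dash difference masks (`.` identity, `-`
deletion — or absent insertion where the consensus itself holds `-` —
and a base letter for a substitution or insertion).
`decode_diff_mask()` and `encode_diff_mask()` are mutual inverses; the
encoder is a small unit-cost global codec (mismatch 1, indel 1.25, so
one substitution is preferred over an indel pair) whose tie-break
prefers deletions and, with the backwards traceback, pushes deletion
runs to the 3′ end — truncated units therefore encode as trailing
dashes, matching the printed tables. This codec is internal plumbing
for the mask format, not a general-purpose global aligner (which the
package deliberately does not expose).

## Tandem-repeat detection and decomposition

`detect_tandem_repeats()` is a purpose-built detector (the analyses it
supports are usually run with an external repeat finder, which is not
scriptable here and whose heuristics are not what we want to verify):

1. **Candidate periods** come from the distance histogram of repeated
   7-mers; distances between `min_period` (default 10 bp) and half the
   sequence length with at least two supporting votes are candidates,
   processed in increasing order so the fundamental period claims an
   array before its multiples can.
2. **Anchoring and walking.** For a candidate period $p$, the
   self-match profile $m_i = [s_i = s_{i+p}]$ is smoothed over
   $p$-wide windows; within each above-threshold run the window of
   maximal self-identity anchors a block that must lie inside the
   array. From the anchor the detector walks in steps of $p$ in both
   directions, accepting blocks whose identity to the evolving array
   consensus is at least `min_identity` (default 80%).
3. **Edges.** One additional *diverged* full leading unit is admitted
   when its identity to the consensus is below threshold but at least
   `divergent_include` (default 50%) — diverged first units are a real
   feature of these arrays and must stay part of the TR, not be pushed
   into the 5NR. A trailing partial unit is grown by exact match to
   the consensus prefix and kept when it reaches `min_partial`
   (default 5 nt). Units always tile from the array start; on arrays
   whose first unit conforms to the consensus this coincides with
   choosing the phase that maximises first-unit-to-consensus identity,
   and it is deterministic in every other case.
4. **Filters and extras.** Calls need `min_copies` (default 1.9)
   copies. Divisor periods at which the array still shows at least 60%
   self-identity are reported as `alt_periods`: a 64-nt unit formed by
   fusing two ~28%-diverged 32-nt halves shows exactly this signature
   (below the 80% threshold at offset 32, far above chance).

Threshold identity cannot localise an array edge more precisely than
about $0.2p$ (a window straddling the boundary still exceeds 80%), so
edges are settled by exact consensus matching; consequently boundary
recovery is exact on substitution-free arrays and within a fraction of
one unit otherwise. Note that a perfectly periodic array whose flank
happens to continue the period is *mathematically* ambiguous — the
array genuinely extends; the simulator therefore pins the single base
on each side of a planted array to break the period, which makes the
planted ground truth the unique answer rather than one of several
equally valid ones.

`decompose_cr()` converts a call into `5NR + units + 3NR` and
guarantees exact concatenation to the input. `build_consensus()` is a
per-column majority over the full-length (modal-length) units, ties
resolved toward the first-observed unit's base; a flagged divergent
first unit does not contribute to the consensus.

## Haplotype statistics and exclusions

`repeat_unit_set()` collapses an array's units into haplotypes with
multiplicities and computes the pairwise similarity matrix. Two kinds
of haplotype are excluded from the similarity range, which is the only
combination consistent with all the published per-species ranges:

- a **divergent initial unit** (identity of unit 1 to the consensus of
  the rest below 90% while all other full-length units are above it);
- haplotypes whose deletion relative to the consensus is **internal**
  rather than terminal. Terminal truncations are kept — local
  alignment trims them naturally, which is how a 14-nt truncated
  haplotype can still register 92.9% against its full-length partner.

Internal-vs-terminal is judged on the *encoded difference mask*, not
on the local alignment: a deletion inside a slippage-prone TATA tract
can score better as an ungapped, slightly mismatched alignment and
would otherwise masquerade as a substitution variant (this exact case
occurs in the *Calandrella cinerea* array, where the mask-based rule
keeps the published 100% range).

`detect_subunit_fusion()` reports an even-length unit whose halves
differ at no more than 35% of positions (the observed fused unit's
halves differ at 9 of 32). `fold_score()` is a Nussinov
base-pair-maximisation (Watson–Crick pairs only, minimum hairpin loop
3 nt) used as a parameter-free stability proxy; thermodynamic free
energies are deliberately out of scope, so published kcal/mol values
are not reproduced, only the qualitative pattern (e.g. a poorly
folding half-unit gains structure inside the fused unit) is examined.

## The seven-pattern homology scan

From a decomposition, `build_patterns()` forms 5NR, the consensus
unit, 3NR, and their concatenations (seven patterns).
`scan_genome()` scans them against the doubled genome sequence (so
origin-spanning homology is not missed) on both strands:
exact 12-mer seeds grouped by diagonal, one local-alignment extension
per diagonal cluster, hits kept at ≥ 85% identity over ≥ 30 columns
(defaults; the interesting observed hit is 100% over ~80 bp, far
above), self-hits overlapping the source rCR2 suppressed, circular
duplicates collapsed, and every hit annotated with the genes it
overlaps (≥ 1 bp intersection). Reported identities are recomputed
from the stored aligned strings in the tests.

## TDRL enumeration

`apply_tdrl()` duplicates a contiguous block in tandem and removes the
specified single copies; `enumerate_tdrl()` tries every block that
contains the CR and ends at its 3′ boundary, starting within a window
(default Cytb..CR — the neighbourhood in which the duplicated-CR avian
orders arise; the window is a configurable constraint, not a claim
that other blocks are impossible), against every loss pattern that
removes exactly one copy of each duplicated non-CR gene. Both CR
copies always survive: degradation of CR2 to a remnant is an
annotation change, not a gene loss. Order equality is up to rotation
only — strand signs must match exactly, since mitochondrial gene
strands are fixed. From the ancestral single-CR order to the
duplicated-CR order exactly three blocks succeed, each with a unique
loss pattern; their intermediates classify as T1/T2/T3 and the number
of contiguous lost fragments (2/2/1) is reported as parsimony
metadata, not enforced as a preference. The enumeration is verified
against an independent brute-force oracle on all tested orders of
length ≤ 8.

## Trait mapping and the repeat-association test

`fitch_ancestral()` performs exact minimum-change ancestral
reconstruction. At binary nodes it is the classical two-pass Fitch
procedure; at multifurcations it uses Hartigan's majority
generalisation (keep the states held by the largest number of
children, add one change per child outside that set), because the
simpler intersection/union extension does not always reach the true
minimum and the package's contract — verified exhaustively on trees of
≤ 10 tips — is that the reported count *is* the minimum. Down-pass
ambiguity is resolved deterministically (parent's state when
available, else the lexicographically smallest), and changes are
recorded on the branches where the resolved state switches;
`origin_branches()` extracts the origins of a derived state, e.g. the
single origin of the remnant-CR2 order on the stem of the
larks-plus-*Panurus* clade in the bundled fixture.

`fisher_exact()` sums hypergeometric probabilities of all tables no
more probable than the observed one (relative slack 1e-7 for
floating-point ties). The published per-species CR1/CR2
repeat-presence table is appendix material not bundled here, so the
package treats that contingency table as user input; the analysis
script demonstrates the test on a synthetic table and the suite
verifies the p-value against exhaustive enumeration and
`stats::fisher.test`.

## The simulator: what it emulates, and what it does not

`simulate_mitogenome()` fabricates an avian-style mitogenome — 13
PCGs, 22 tRNAs, two rRNAs, the control regions implied by the chosen
order type, ND6 and the eight usual tRNAs on the L strand — with a
CR1 assembled from planted conserved-box motifs in domain order and an
rCR2 built by `simulate_cr2()` as `5NR + units + 3NR`. Defaults for
the rCR2 (60-nt 5NR, 4 × 37-nt units, 40-nt 3NR) mirror a typical
lark-scale array. Units derive from a random master unit with
per-unit substitution rate 0.01 by default (published arrays show no
point mutations among non-initial units, but a small nonzero default
keeps haplotype multiplicity code honest); options plant a strongly
diverged first unit (~25% of positions substituted, emulating the
D1/F1/G1 pattern), a fused master unit whose halves differ at
`round(0.28 · p/2)` positions (9 at period 64, the observed case), a
fractional trailing copy, and a copy of the 3NR's 3′ end at the rrnS
5′ end (at most 81 nt — the observed homology event) for the scan
stage. Gene sequences are random with correct ATG/TAA frames; PCG
length draws are scaled to an approximate 17 kb genome target.

The simulator does **not** emulate real base composition (so skews
hover near zero), substitution-model heterogeneity, concerted
evolution between CR1 and CR2, heteroplasmy, or realistic tRNA/rRNA
structure. Passing tests on simulated data therefore demonstrate that
the *structural* logic — boundaries, classification, enumeration,
recovery — is correct, not that the detector's thresholds are tuned
for every real-data pathology. All randomness flows from one integer
seed (sub-seeds at fixed offsets per component), and regeneration is
byte-identical; consumer tests read simulated data only through the
public FASTA/TSV/Newick formats.

## Numerical choices and problem sizes

Detector defaults: `min_period` 10 bp, `min_copies` 1.9,
`min_identity` 80%, divergent-unit floor 50% (well above the ~25%
identity of random DNA at these lengths), minimal partial unit 5 nt,
alt-period floor 60%. Scan defaults: 12-mer seeds, 85% / 30 bp
thresholds. Divergent-initial threshold 90%. Fusion threshold 0.35
of the half-length. Fold minimum loop 3 nt. The property suites run
at sizes where exhaustive oracles are exact and fast: enumeration
alignment oracles at ≤ 6 nt, brute-force TDRL at ≤ 8 genes, exhaustive
Fitch at ≤ 10 tips, Fisher enumeration at n ≤ 20, folding enumeration
at ≤ 15 nt, and a 50-array recovery study (periods 20–70, 2–8 copies,
substitution rate up to 0.02) for the detector, chosen to exercise the
lark-realistic parameter range while keeping the whole suite around
half a minute.

## Known limitations

- The detector reports non-overlapping arrays with a single period
  each (plus divisor alternatives); genuinely nested or interleaved
  repeat structures are out of scope.
- Identity-thresholded boundaries are exact only up to the edge
  conventions above; on heavily mutated arrays the copy count is
  reliable to about one partial unit.
- The homology scan extends one alignment per seed-diagonal cluster;
  a composite pattern whose best in-window alignment lies inside the
  excluded source region is suppressed rather than re-aligned
  elsewhere (the component patterns still report such hits, which is
  the event of interest).
- `fisher_exact()` and `fitch_ancestral()` are exact but enumerative /
  combinatorial on small inputs by design; they are not optimised for
  hundreds of states or tables with counts in the thousands.
- Free-energy folding, de novo annotation, tree inference and
  divergence dating are intentionally not implemented; trees and
  annotations are inputs.
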