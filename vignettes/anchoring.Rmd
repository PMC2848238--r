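---
title: "Anchor-based divide-and-conquer alignment: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-based divide-and-conquer alignment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AnchorAlign)
```

## The model

AnchorAlign assumes its inputs are *globally collinear* homologous
nucleotide sequences: the same segments in the same order, diverged by
substitutions and indels.  Under that assumption, a k-tuple found exactly
once in every sequence — allowing at most one substitution — is very
unlikely to be coincidental and very likely to mark the same homologous
locus everywhere.  The package's whole strategy is to find such k-tuples
(*seeds*), discard the mutually inconsistent ones, fix the survivors as
gap-free *anchor* columns, and align only the short regions in between.

The back-of-envelope that calibrates k: a random sequence of length A
contains about A/4^k occurrences of each k-tuple, so the informative
lengths are those with A/4^k near 1, i.e. k near log4(A).  Real sequences
are not random — conserved regions admit longer useful k-tuples, while
non-conserved (effectively random) stretches are what ultimately limits the
method.  Because "too small" cannot be predicted in advance, *all* k from 1
to M are indexed, with M bounded by memory/addressing considerations rather
than biology.

### Dictionary semantics

For every k ≤ M and every k-tuple over {A,C,G,T} occurring in the data the
dictionary stores: the exact occurrence count (overlapping windows all
count), the number of distinct sequences containing it, and the index of
the last sequence where it was seen.  The last-sequence index is what makes
the distinct-sequence count computable in a single read: a new occurrence
increments the sequence count only when it comes from a different sequence
than the last one recorded.  The implementation integer-encodes each
sequence once (2 bits per base) and derives all window codes for all k
arithmetically from that encoding, so the residues are read exactly once;
the unit tests assert this with an instrumented pass counter.

Windows overlapping any non-ACGT character are skipped entirely.  The
4-letter alphabet is a modelling assumption (there are 4^k possible
k-tuples), and assigning ambiguity codes to counts would blur exactly the
uniqueness signal the method relies on.  Ambiguous residues still flow
through alignment and output untouched.

The *inexact count* of k-tuple t is its exact count plus the exact counts
of its 3k one-substitution (Hamming-1) neighbours.  Insertions, deletions
and double substitutions are deliberately outside the neighbourhood: a
fixed-length substitution-only neighbourhood keeps the counts additive and
the second-pass verification exact.

### Two-stage seed verification

"One inexact match in every sequence" is enforced in two stages:

1. aggregate prefilter — inexact count equals N (a necessary condition
   computable from the dictionary alone);
2. per-sequence verification — a second read locates all Hamming-≤1
   windows of each candidate and keeps it only if *every* sequence has
   *exactly one*.

The aggregate dictionary cannot by itself certify per-sequence uniqueness
(all N inexact matches could sit in one sequence); the location pass is the
natural place to check, and everything downstream assumes seeds occur at
most once per sequence.

### Ranking, the cap T, and overlap-aware selection

At most T seeds (default 600) enter conflict resolution; the T×T distance
matrix is the quadratic part of the algorithm and T bounds it.  "Best" is
defined by a deterministic key: longer k first (a longer exact shared
k-tuple is a stronger homology signal), then exact matches in more
sequences, then smaller coordinate in sequence 1, then the k-tuple string.

Selection is *overlap-aware*: walking down the ranking, a seed whose window
overlaps an already-selected seed's window in any sequence is skipped.  In
low-divergence data nearly every position carries a top-ranked seed; a
blind top-T would then select ~600 mutually overlapping seeds clustered at
the smallest coordinates, anchoring only the first ~T bases and forcing
deep recursion over the rest.  Skipping overlaps costs nothing in the
sparse-seed regime (it is a no-op there) and spreads anchors across the
sequences in the dense regime.  The non-overlap removal pass inside
conflict resolution is kept regardless, so the anchor-set invariants never
depend on the selection heuristic.

### Incompatibility distance and conflict resolution

For seeds A and B, each sequence orders their unique occurrences either
A-before-B or B-before-A; the incompatibility distance is the number of
sequences departing from the majority order.  Two conventions the distance
definition leaves open are fixed as follows: a window *overlap* within a
sequence counts against both orders (overlapping anchors would make segment
boundaries ill-defined), and an exact tie takes the order in sequence 1 as
the majority (the distance value itself is unaffected).

Resolution iteratively removes the seed with the largest row sum —
breaking ties by removing the worst-ranked seed — and re-derives the
matrix.  Since the distance is purely pairwise, re-derivation after removal
is exactly row/column deletion; nothing else changes.  The loop terminates
with an all-zero matrix, and with everything pairwise-conflicting it
terminates with a single seed, so a non-empty input always yields at least
one anchor.  A second, identical removal loop on the overlap-violation
matrix then guarantees pairwise non-overlap in every sequence.  These
invariants are enforced as S4 validity conditions of the anchor-set class:
it is impossible to construct a non-collinear `AnchorSet`.

### Division, recursion, assembly

Anchors contribute their windows as gap-free blocks (a seed window is by
construction at most one substitution from the k-tuple — no indel can occur
inside it, so no gaps are needed).  Inter-anchor segments are aligned
independently and the parts concatenated in order.  A segment whose longest
interval is at most `segmentThreshold` (default 2000 bp — conservative for
what conventional aligners handle comfortably) goes to the sub-aligner;
longer segments are re-anchored recursively.  Depth counts anchoring
rounds, top level = 1; `maxDepth = 1` therefore means "anchor once, then
sub-align everything", the recommended mode for closely related sequences
where good seeds abound in the first round.  A recursion that finds zero
anchors falls through to the sub-aligner regardless of length; zero anchors
at the top level sends the whole dataset to the sub-aligner.  Anchor
windows are kept whole even when the permitted substitution falls at a
window edge — trimming would complicate coordinates for no measurable
benefit.

In seeds-only mode no sub-aligner ever runs: leaf segments are
left-justified and gap-padded to the widest interval.  The result is a
*rough* alignment — anchor columns are aligned, inter-anchor residues are
merely stacked — suitable for eyeballing large indels and for dataset
triage, not for downstream analysis.

### Scoring

The sum-of-pairs identity score S_ij = 100·M_ij/L is taken literally:
L is the full alignment width including gaps, and M_ij counts columns where
both rows carry the same non-gap character.  Consequently a column gapped
in both rows contributes to L but never to M_ij, and appending an all-gap
column strictly lowers every pairwise score — a property the tests assert.
Comparison is literal character equality after uppercasing, so N matches N;
given that ambiguity codes never enter seed finding, this only affects the
reported score, and only when ambiguity codes are abundant.

## Sub-aligners

The builtin segment aligner is a progressive profile aligner: sequences are
added longest-first to a growing profile by global affine-gap dynamic
programming (Gotoh's three-state recurrence, implemented in C++), a profile
column scored as the mean substitution score of its residues with gaps
scoring as gap extensions.  Defaults — match 1, mismatch −1, gap open −4,
gap extend −1, a gap of length g costing open + g·extend — are conventional
nucleotide values.  Tie-breaking prefers the diagonal, then the column-gap,
then the residue-gap state, making output deterministic.  For two sequences
this is exactly optimal pairwise alignment, verified against an independent
exhaustive DP oracle in the tests.  Length-descending guide order (rather
than a guide tree) is deliberate: inter-anchor segments are short and
similar, where tree estimation adds cost and dependency for negligible
gain.

The external adapter runs any `FASTA in → aligned FASTA out` command
(templates provided for MAFFT and CLUSTAL W), restores input order if the
tool reorders records, and *verifies the round-trip invariant on the tool's
output* — a misbehaving tool aborts the run rather than corrupting the
alignment.

## The simulator, and what passing tests do and do not show

`randomSequences()` generates i.i.d. uniform ACGT sequences — the standard
negative control: such data share no homology, and seed finding should come
up empty.  `evolveFamily()` evolves n descendants independently from one
random ancestor (star phylogeny) with per-site substitutions (default
regimes used in testing: 0, 0.003 — matching the nucleotide diversity of
human mitochondrial genome samples — and 0.05), per-site indel events with
geometric lengths (mean 3 bp), and records every edit plus the monotone
ancestor→descendant coordinate map.  `plantConservedMotif()` writes a
clash-free k-mer at one homologous coordinate in every sequence with
re-randomized flanks — emulating a perfectly conserved site inside a
variable region — so anchor recovery can be checked against ground truth.

What this emulates well: point divergence, small indels, conserved
landmarks, unalignable noise.  What it does not: rate heterogeneity along
the sequence, tree-structured relatedness, rearrangements, duplications,
inversions, or base-composition bias.  Passing the battery therefore shows
the machinery is correct under the collinear model, not that the method
detects model violations — by construction it cannot (see Limitations).

Problem sizes used in the shipped tests and acceptance script — chosen as
the smallest sizes at which the studied regimes actually express
themselves: the unalignability control uses 50 × 20 kb random sequences
(at that N, chance seeds are effectively impossible, so "zero seeds" is the
unambiguous expected answer); anchor recovery uses 20 replicates of
n = 50 × 16.5 kb at 0.3% substitutions, the mitochondrial-genome regime;
round-trip batteries span n ∈ {3, 5, 10}, ancestors 5–50 kb,
substitution rates {0, 0.003, 0.05}, with and without indels.

## Numerical and representation choices

- k-tuples are 2-bit-encoded integers (A=0, C=1, G=2, T=3, most significant
  first); with the hard cap M ≤ 14 (default refusal point; 4^15 − 1 is the
  last code fitting a 32-bit signed integer) all codes are plain R
  integers.  The dictionary is sparse — only occurring k-tuples are
  materialized, as per-k tables keyed by code; a dense 4^k vector is built
  only transiently inside inexact-count computation (k ≤ 12) for O(1)
  neighbour lookup.
- Coordinates are 1-based, closed intervals, the IRanges/Biostrings
  convention, everywhere including the anchors TSV.
- All tie-breaks (ranking, removal, DP traceback) are fixed and documented;
  two runs on the same input are bitwise identical, and the simulator runs
  on a private RNG state so it neither depends on nor disturbs the
  session's.
- Degenerate inputs have defined behaviour: empty segments yield width-0
  alignments; a sequence with an empty interval gets an all-gap row;
  width-0 alignments score 0 with a warning; an empty candidate list
  short-circuits to the no-seed path.

## Limitations

- Rearrangements, duplications, inversions and translocations violate the
  collinearity assumption and are not detected; anchors spanning such
  events are resolved away as incompatible, and the affected regions fall
  to the sub-aligner, which will produce a (poor) collinear alignment
  rather than a warning.
- Strand is not considered: sequences must be supplied in the same
  orientation.
- Seeds occurring more than once in a sequence are discarded rather than
  disambiguated, so highly repetitive genomes yield few anchors.
- The sum-of-pairs identity score divides by the full alignment width,
  so scores from alignments of different widths are not directly
  comparable.
- The builtin progressive aligner is a correctness-first reference
  implementation intended for inter-anchor segments; for whole large
  datasets with no anchors, an external aligner is the right tool, and the
  builtin refuses beyond a size cap rather than running for hours.
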