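---
title: "grnakit: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{grnakit: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grnakit)
```

This vignette documents the scientific model behind each `grnakit`
component, the conventions and parameters that shape results, and the
choices made where the design was genuinely open. It states no numbers
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The editing system being modelled

Type I-B CRISPR-Cas systems target DNA through a multi-subunit Cascade
complex guided by a crRNA; the recruited Cas3 nuclease-helicase then
degrades DNA processively from the cut. In a host expressing thermostable
NHEJ enzymes (Ku and LigD), the degraded region is resealed, leaving a
deletion whose extent varies from event to event — from roughly a
kilobase to beyond 200 kb around one target site. Two empirical facts
organize the toolkit:

* recognition requires a TTA protospacer-adjacent motif (PAM) located 5'
  of the protospacer on the protospacer's own strand;
* editing efficiency splits sharply by guide GC content: spacers under
  50% GC edit efficiently, spacers at or above 50% almost never.

## Coordinates

Internally every interval is a Bioconductor `GRanges`/`IRanges`: 1-based,
closed. This is deliberate — the surrounding ecosystem (overlap queries,
interval unions, GFF3 import) is native to that convention, and using it
end-to-end eliminates conversion points inside the package. The 0-based
half-open convention appears only at external surfaces, produced by the
writers in a single file (`io.R`): BED output, and the `spacer_start`/
`spacer_end` and `del_start`/`del_end` columns of the manual and calls
TSVs. GFF3 input is 1-based inclusive and is kept as-is. One direction to
remember: a GFF3 feature `101..200` has width 100 and is written to BED
as `100 200`.

## Guide design

`enumerateSpacers()` scans both strands of every contig for every PAM in
the configuration (default `TTA` only, since that is the evidenced PAM;
the set is configurable because the full repertoire of the I-B system is
not established). Each PAM occurrence with a full-length window
immediately 3' of it (on its strand, inside the contig) yields exactly
one candidate. Windows containing `N` are dropped: an ambiguous base
makes both the GC score and the guide sequence unreliable, and a genome
assembly gap is not a targetable site.

Parameters (`designConfig()`):

* **Spacer length, default 30 nt, floor 27.** Truncation experiments
  established that spacers of at least 27 nt retain cleavage function;
  below that nothing is validated, so the package refuses shorter
  spacers rather than warning. The native length is configurable.
* **GC is computed over the spacer only**, excluding the PAM. The PAM is
  constant across candidates, so including it would shift every value by
  the same amount without changing any ranking; excluding it keeps the
  reported percentage interpretable as a property of the guide.
* **Efficiency class**: `high` iff `gc < 0.50` (`classifyEfficiency()`).
  The boundary goes to `low` because the efficient class was observed
  strictly below 50%; a 50%-GC guide has no evidence of working.
* **Tm (`meltingTemp()`)** is reported for information only and never
  used in ranking: the mechanistic hypothesis that lower-Tm guides
  release the effector complex more easily did not survive the
  truncation experiment, so Tm stays descriptive. Default estimator is
  the GC formula `81.5 + 0.41·%GC − 675/N` for N ≥ 14 and the Wallace
  rule below that (the Wallace rule is the standard short-oligo
  estimator; the GC formula diverges badly at very short lengths).

`selectManual()` assigns candidates to genes by **full containment**: a
cut anywhere within the gene disrupts it, and containment is unambiguous
where mere overlap would require an arbitrary threshold. A candidate
inside two overlapping genes is assigned to both — it genuinely targets
both. Per gene, the `perGene = 3` candidates with the smallest GC are
selected; ties break by (GC, forward-strand start, `+` before `-`), a
total order that makes manuals byte-reproducible across runs. Genes with
fewer than three candidates contribute what they have, with a warning
rather than an error — a sparse gene is a property of the genome, not a
failure.

## Junction calling

The caller (`inferDeletion()`) formalizes what one does by eye with a
Sanger trace across a repair junction: find where the read stops matching
the upstream reference and resumes matching downstream.

Both flanks are anchored by an exact seed — the first and last
`minFlank` (default 30) bases, located with up to
`maxMismatchRate × minFlank` mismatches (default 0.05, Sanger-quality) —
and then extended by **exact** matching. With prefix support `a` at
genome offset `pL`, suffix support `b` ending at `pE`, and read length
`n`, the overlap `a + b − n` decides the junction type:

* overlap ≥ 0: microhomology of that many bases. The breakpoints are
  shift-equivalent over `m + 1` placements; the call is reported
  **leftmost** (the VCF convention), with `microhomology_len = m` making
  the ambiguity explicit rather than hiding it.
* overlap < 0: the unaligned middle is a non-templated insertion. When an
  insertion's edge bases happen to match adjacent deleted reference, they
  are absorbed into the flanks, i.e. the minimal-insertion representation
  is canonical.

Why exact extension rather than mismatch-tolerant? Beyond the true
junction the read continues against effectively random sequence, which
still matches one base in four; a tolerant extension can drift many
bases past the junction through chance matches while staying under a 5%
mismatch budget, silently corrupting the microhomology arithmetic. Exact
extension stops at the first disagreement, which is precisely the
junction definition. The cost is that a *sequencing error* inside a
flank truncates its support — acceptable for Sanger-quality input and
the clean reads the simulator produces, and a documented limitation for
noisier data.

Only same-contig, same-orientation two-anchor events are called.
Anchors on different contigs raise a `grnakit_translocation_like` error
(reported, not called — such events are real but out of scope), no
confident anchor raises `grnakit_unmapped_flank`, and a read that is a
contiguous reference slice raises `grnakit_no_deletion`. The vectorized
`inferDeletions()` collects these per-read failures with reasons instead
of failing the batch.

Downstream statistics are set algebra: `unionIntervals()` reduces calls
per contig; `genomeCoverageStats()` reports the union in kb (3 decimals,
matching how such lengths are quoted) and as a percentage (2 decimals
plus a rounded integer); `callNonessential()` lists genes **fully
contained** in the union — containment again, because a partially
degraded gene is not proven dispensable — sorted by coordinate. The
package ships `PTG_GENOME_LENGTH_BP = 3.9e6`, an approximate total
genome length for the target strain used as a default denominator; users
with the assembly should pass the genome (or its exact length) instead.

## Homolog screening

The pipeline that selected thermostable NHEJ candidates is reimplemented
end to end; the database search that produces the initial hit list is
out of scope (input is a user-supplied FASTA).

* `globalIdentity()`: Needleman–Wunsch global alignment, match +1,
  mismatch 0, linear gap −1 per residue (end gaps penalized), in C++.
  Among score-optimal alignments the implementation maximizes the match
  count with a second dynamic program, so identity does not depend on
  traceback tie-breaking. Identity = matches / **shorter** sequence
  length — the CD-HIT convention, stated explicitly because it changes
  cluster membership near thresholds. Substitution-matrix scoring is
  deliberately out of scope: identity counting, not alignment quality,
  is what the downstream thresholds consume.
* `filterByIdentity()` keeps candidates **strictly above** the cutoff
  (default 0.45), matching a "more than 45%" selection rule.
* `greedyCluster()` is CD-HIT's greedy incremental scheme: sort by
  length descending (ties by id in C locale), join the first cluster
  whose representative is within the threshold (default 0.75), else
  found a new one. By construction the representative is the longest
  member and every member satisfies the identity invariant, which the
  tests assert on every output.
* `njTree()` is the Saitou–Nei neighbor-joining algorithm on a distance
  matrix, by default `1 − identity` from pairwise global alignments —
  deliberately *not* from a multiple sequence alignment. Pairwise
  p-distances are reproducible without an MSA step and suffice for
  picking screening representatives; this is a documented deviation from
  MSA-based workflows, not an emulation of them. NJ recovers the true
  tree exactly on additive matrices (the tests verify this on random
  trees of 4–8 taxa); negative branch-length estimates, which arise on
  non-additive data, are clamped to zero with a note. Pair-selection
  ties break by matrix order and branch lengths are formatted with a
  fixed `%.12g`, so identical inputs give byte-identical newick.
* `pickRepresentatives()` cuts the longest internal edges (then, if more
  groups are requested than internal edges exist, the longest terminal
  edges) until the requested number of leaf groups exists, then returns
  each group's medoid — the leaf with the smallest mean patristic
  distance to its group. The number of branches is an input (default 5),
  not auto-detected: the original choice of five branches was a
  judgment call on a specific tree, not an algorithm.

## The synthetic-data generator

The generator exists so that every stage has machine-checkable truth
without downloads. Defaults are chosen once to emulate the study system
at bench scale:

* single contig, 100 kb (desk-scale stand-in for a ~3.9 Mb genome),
  i.i.d. bases at 44% GC — the target organism's genome-wide GC is in
  the mid-forties, and at that composition TTA occurs abundantly by
  chance (~2% of positions per strand), so the additional planted TTA
  site per kb mainly guarantees coverage in GC-rich stretches;
* 50 non-overlapping genes of 0.3–2.4 kb, a typical bacterial gene-length
  range, placed by stick-breaking of the intergenic space;
* per-side deletion extents log-uniform on [1 kb, 210 kb], truncated at
  contig bounds. Observed deletion spectra are broad and heavy-spread
  across 1–209 kb but fit no stated distribution; log-uniform spans that
  range with equal weight per decade and is explicitly a stand-in — the
  true Cas3 extent distribution (and any left/right asymmetry) is
  unknown. The distribution is a config field, not hard-coded;
* junction microhomology of 1–5 bp with probability 0.3 and non-templated
  insertions of 1–5 bp with probability 0.1 (typical NHEJ junction
  features; the two are drawn mutually exclusively for clarity of
  truth); 400 bp flanks, a conservative Sanger read half-length.

Two generator properties matter for interpreting test results:

1. **Truth is realized, not merely planted.** At ~25% per side, random
   junctions carry chance microhomology; after all reference edits the
   generator recomputes each event's leftmost-normalized breakpoints and
   microhomology from the final sequence by direct base comparison, and
   records insertions in the same canonical (flank-absorbed) form the
   caller reports. Caller and generator therefore share one convention,
   and "exact recovery" in the tests means string-level agreement on
   that convention, not luck.
2. **Determinism.** Each `simulate*` function seeds R's RNG locally and
   restores the caller's RNG state on exit; identical seeds give
   byte-identical FASTA/GFF3/reads, which the determinism tests check at
   file level through the CLI.

What the generator does **not** emulate: codon structure and operons,
sequencing errors (beyond seed-level mismatch tolerance in the caller),
GC heterogeneity along the genome, repeated sequence. Passing tests
therefore demonstrate algorithmic correctness under clean, unambiguous
anchoring — they do not certify performance on repetitive regions or
low-quality traces, where seed anchors can become non-unique and flank
support can truncate.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to exercise the
algorithms well past toy scale while staying desk-fast: 20 synthetic
genomes (16 × 20 kb, 4 × 50 kb) for exhaustive design-oracle equivalence,
2 × 200 junction reads on 100 kb genomes for breakpoint recovery, 100
random 4–8-taxon additive matrices for NJ exactness, and 150-residue
protein families for clustering. Distance-matrix symmetry is required to
1e-8; NJ branch-length recovery is asserted to 1e-9; identity and GC
comparisons use exact or 1e-12 tolerances since both are ratios of small
integers.

Known limitations, beyond those listed above: the caller assumes exactly
one junction per read (multi-junction reads would need recursive
splitting); gene assignment ignores strand (a guide cuts DNA, not a
transcript); and greedy clustering is order-dependent by design —
faithful to CD-HIT, but a different sequence order convention would
yield different (equally valid) clusterings, which is why the sort order
is fixed and documented.
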