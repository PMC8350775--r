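---
title: "Methods: structural analysis of circular plant mitochondrial genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural analysis of circular plant mitochondrial genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoring)
```

## The problem

Plant mitochondrial genomes (mtDNA) are large (hundreds of kb), carry pairs
of long near-identical repeats, and recombine across those repeats at high
frequency.  As a consequence a species' mtDNA is not one sequence but a set
of structural *isoforms*: alternative circular arrangements of the same
content, interconvertible by homologous recombination.  Inverted repeat
copies invert the intervening segment; direct copies split one circle into
two subgenomic circles, or fuse two circles into one.  The same repeats
complicate assembly: short-read contigs break at repeats, and long-read
contigs end inside them, so finishing a "master circle" requires explicit
structural reasoning (terminal-overlap circularization, repeat-mediated
circularization, recombination-like merging).  Plant mtDNA additionally
accumulates insertions of plastid DNA (MTPTs) and undergoes extensive
C-to-U RNA editing of its coding sequences.

`mitoring` implements this analysis stack end to end: repeat discovery and
naming, assembly finishing, isoform equivalence testing, MTPT detection and
cross-species classification, editing-site calling with functional effects,
and coding-sequence divergence with neighbor-joining trees — plus a seeded
synthetic-genome generator so that every component is testable against
known ground truth without any downloads.

## Coordinates and circular topology

All internal coordinates are 0-based half-open; conversion to the 1-based
conventions of GFF3 and pileup files happens only at file boundaries, and
user-facing reports echo 1-based positions.  Features spanning the origin
of a circle are stored as `start > end` with a `wraps` flag; GFF3, which
has no native circular support, receives them as two parts sharing an `ID`
and rejoins them on read.  `rotate()` and `reverse_complement()` remap all
annotations, and the package treats any rotation or reflection of a circle
as the same molecule (canonical forms are minima over rotations and the
reflected, sign-flipped sequence).

## Repeat discovery

`find_repeats()` seeds with exact 24-mers on the doubled sequence (so
copies may span the origin) and extends seed clusters greedily without
gaps, tolerating mismatches under an x-drop score (+1 match, −3 mismatch,
drop 15).  The gap-free model is deliberate: the repeats that matter for
recombination in these genomes are near-identical (default identity floor
0.99), and indel-free extension keeps every reported pair re-verifiable by
direct sequence comparison.  At `min_identity >= 0.999` the engine switches
to *exact mode* — contiguous seed runs and mismatch-free extension — whose
output provably equals the set of maximal exact repeated pairs; the test
suite checks this against an independent brute-force oracle that scans
every diagonal and anti-diagonal of the byte matrix.

Conventions follow the field: pairs are named `R01…Rn` strictly by
descending length (ties by position), copies of a family with more than two
copies are reported as all pairwise combinations plus a `family` grouping
label, tandem-like hits whose copies share more than half their span are
suppressed, and homologous repeats in a second genome inherit the reference
names by reciprocal best k-mer containment (which also captures an expanded
homolog that contains the reference copy).  `count_repeat_pairs()` counts
*families*, so a triple-copy repeat contributes one — the natural reading
of a published count of "pairs of repeated sequences".

## Assembly finishing

Three operations reproduce the structural logic used to close these
genomes:

* `circularize_by_terminal_overlap()` finds the longest prefix ≈ suffix
  match (identity ≥ 0.99, tolerating long-read error; the junction keeps
  the prefix copy's bases) and removes one copy: a contig of length
  `L + o` circularizes to `L`.
* `circularize_via_repeat()` handles contigs whose two ends are partial
  fragments of one repeat: the fragments are completed into a single full
  copy, giving `len(contig) − x − y + len(repeat)`.
* `merge_circles_by_repeat()` performs a recombination-like fusion at a
  shared repeat (auto mode picks the longest shared segment).  The
  crossover is placed at the repeat midpoint — the paper-scale choice is
  arbitrary but sequence-neutral because the copies are near-identical —
  and the product is one circle of exactly `len(a) + len(b)` carrying two
  copies of the repeat.

Length conservation under merging, and the inverse relationships
(`fragment_with_overlap` → circularize; `split_by_direct_repeat` → merge)
are property-tested.

## Isoform equivalence

`decompose_blocks()` reduces two circles to a shared-block representation:
anchors are 31-mers (strand-collapsed) unique in both genomes and outside
repeat copies; maximal co-linear anchor runs — broken wherever the run
would straddle a repeat copy in either genome, at sign changes, at
offset drift > 50 bp, or at gaps > 5 kb — become blocks (A, B, C, … by
descending size).  Each genome is then a circular signed sequence over
block and repeat-copy symbols.

`recombination_moves()` generates the neighbor states: inversion between
inverted copies of a family on one circle, fission at direct copies,
fusion of two circles at one copy each.  `are_isoforms()` runs a
breadth-first search from one arrangement to the other's canonical form.
Intermediates may be multi-circle — two direct-repeat events (fission then
fusion at a second family) produce single-circle translocations these
genomes exhibit, and subgenomic circles are biologically real — but
verdicts are judged at single-circle endpoints.  Only families ≥
`min_repeat` (default 500 bp, the size class engaged in frequent
reciprocal recombination) generate moves; smaller events such as a 122 bp
intermediate-size repeat are surfaced by `structural_diff()` instead,
which also reports per-block placements, private segments, repeat-length
differences (e.g. a 3.5 kb family expanded to ~10 kb) and copy-number
differences.  Search caps return an explicit `"undecided"` status, never a
silent "not equivalent".  The engine is validated against an independent
oracle that enumerates reachable states on the raw DNA strings.

## Plastid insertions

`find_insertions()` reuses the seed-and-extend engine across genomes with
16-mer seeds (so somewhat diverged transfers still seed) and a default
identity floor of 0.85, chosen to tolerate older transfers; the paper
states no threshold, and planted-recovery tests run at identity 1.0.
Co-linear segments within 100 bp merge; overlapping calls are trimmed so
calls are disjoint on the mitochondrial side; hits inside the second copy
of the plastome's large inverted repeat are collapsed onto the first; and
every plastid gene overlapping the matched interval by ≥ 1 bp is
attributed (published inserts are labelled by gene fragments, so partial
overlap counts).  Both mt-side and cp-side lengths are reported; the
mt-side length is primary.  `classify_insertions()` clusters calls across
genomes by ≥ 50% reciprocal plastid-interval overlap, labels clusters
shared/variable, and flags mutually exclusive variants at one
mitochondrial locus by matching the upstream flanking sequence of the
insertion sites.

## RNA editing

The caller is a transparent threshold rule rather than a black-box variant
caller: a site is called iff depth ≥ 10, the position is inside a CDS, and
the strand-consistent edited fraction ≥ 0.1 — reference `C` with `T` reads
for `+`-strand genes, reference `G` with `A` reads for `-`-strand genes
(counts are always on the reference forward strand).  All other variant
classes are discarded, mirroring the non-C-to-U filter of the original
pipeline; both thresholds are exposed on the CLI.  Effects come from
in-silico editing of the codon under the standard code: `ACG→AUG` in the
first codon is a start gain; a site under several overlapping CDSs yields
one effect record per frame, reproducing the serine→leucine edit in one
frame that creates a stop in the overlapping frame.  The m1A diagnostic
simply reports the T fraction at a position and flags a genomic `A` with a
fraction in [0.3, 0.7] — the signature of reverse-transcriptase
misincorporation opposite 1-methyladenosine.

A deliberate limitation: multi-exon CDS parts are each assumed to start in
frame (no GFF phase tracking).  The biologically salient cases here are
single-exon configurations; trans-spliced frame bookkeeping would need
phase-aware annotations.

## Divergence and trees

Concatenated coding sequences are extracted in alphabetical gene order
(deterministic across genomes; a missing gene is an error, never silently
skipped).  `align_pair()` is an optimal global affine-gap alignment
(match 1, mismatch −2, gap open −5, extend −1) delegated to Biostrings;
inputs over 50 kb switch to anchored mode — unique shared 31-mers chained
by longest increasing subsequence, optimal alignment between anchors —
tested to give identical SNP/gap counts.  "Gaps" are counted as indel
*events* (maximal runs), the standard reading of published SNPs-and-gaps
tables pairing small comparable integers; gap columns are reported
alongside for transparency.  p-distances exclude any column with a gap in
either row, keeping the distance consistent with the SNP count.  Neighbor
joining is implemented classically (Q-criterion; ties by smallest index
pair; negative branch lengths clamped to zero with the remainder moved to
the sister edge) and is exact on additive matrices — verified on random
trees with `ape` as the independent oracle.  Maximum-likelihood trees and
bootstrap are out of scope; the organellar trees being reproduced were
built by neighbor joining.

## The synthetic world

`generate_mitogenome()` plants repeats (direct/inverted/nested), genes
(random non-stop codons; a built-in template of 33 protein genes + 3 rRNAs
with generic organellar names), plastid-derived insertions copied from a
generated plastome, and partial editing sites (a forced `C` on the coding
strand; edited counts are Binomial(depth, extent)) into an i.i.d.
background at GC 0.45.  Defaults mirror the stated world of the source
study: genomes are exercised at the published sizes where a criterion
names them (171,852 / 112,968 / 78,504 / 363,324 bp; 5,225 bp overlap;
repeat sizes 34,696 / 10,430 / 3,553; insert catalogue 194 / 116 / 81 /
198 / 57 / 72 / 1,239 / 354 / 2,253 bp; editing extents 0.89 and ~0.5),
and at reduced scale elsewhere, with the reduction stated in the test.

Two hygiene passes make planted truth *the* truth: emergent exact
duplicates ≥ 25 bp outside planted features are broken by point
substitution, and 3 bp of background flanking every planted copy are
forced to differ from their counterparts, so no detector can legitimately
extend past a planted boundary.  What a green test establishes is
therefore exact recovery of a known combinatorial structure under an
idealized error model (i.i.d. background, uniform sequencing error ε,
binomial editing); it does not establish robustness to real low-complexity
sequence, heteroplasmy, or mapping artefacts, which are outside this
package's boundary (read mapping and upstream assembly are explicit
non-goals).

## Numerical choices

* Seed sizes: 24 (repeats, shared segments), 16 (plastid insertions),
  31 (unique anchors) — chosen so that random collisions are negligible at
  genome scale while diverged homology still seeds.
* x-drop: +1/−3, drop 15 (20 for insertions); identity floors: repeats
  0.99, insertions 0.85, terminal overlaps 0.99.
* Isoform search: `max_moves = 6`, `max_states = 1e5`; block anchor drift
  tolerance 50 bp; private segments reported from 100 bp.
* All stochastic functions take explicit seeds and restore the caller's
  RNG state; identical seeds give byte-identical output.

## Known limitations

Gap-free repeat model (an indel inside a repeat splits it into two
families); no microhomology search; frame-naive multi-exon effect
annotation; the isoform verdict reports *a* shortest move path, which is
not claimed to be the historical recombination path; accession-based
reproduction of the published counts (17 repeat pairs, 738 editing sites,
15 SNPs) requires the deposited data and mapping stack and is outside the
desk-scale test world.
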