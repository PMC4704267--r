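---
title: "Map-driven assembly curation with mapforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Map-driven assembly curation with mapforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapforge)
```

# The problem

Draft plant genome assemblies anchored with sparse genetic maps routinely
carry three classes of error at the scaffold scale: blocks placed in the
wrong orientation, blocks placed on the wrong chromosome, and scaffolds
left unanchored altogether. A dense linkage map built from large
recombinant inbred line (RIL) populations provides an independent,
meiosis-based ordering of markers; wherever genetic order and assembly
order disagree systematically, the assembly is suspect. `mapforge`
implements this curation loop end to end: genotype QC, marker binning,
LOD-threshold linkage grouping, marker ordering with Kosambi distances,
genetic-vs-physical concordance analysis producing a correction ledger,
scaffold anchoring, Marey-map delimitation of heterochromatin, and
in-silico placement of SSR/SNP markers on a corrected assembly sequence.

Because the genotype matrices of real mapping populations of this scale
are rarely redistributable, the package is organized around a first-class
synthetic-data module: a seeded simulator of F5-derived RIL populations
over a configurable model genome, plus a corruption engine that plants
inversions, translocations and detached scaffolds with a machine-checkable
truth ledger. Every downstream stage is exercised against that truth.

# The simulator

`simulate_population()` descends each line from a single F1 by `k` rounds
of self-fertilization (`selfing_generations = 4` gives F5-derived lines,
the default). Meioses follow a no-interference (Haldane) crossover
process on the true genetic scale defined by each chromosome's Marey
knots. At marker resolution this process is realized exactly as a
two-state Markov chain: a gamete starts on either parental haplotype with
probability 1/2 and switches between adjacent markers with probability
equal to the Haldane recombination fraction of their genetic separation.
This is not an approximation — for readout at fixed marker positions the
chain is distributionally identical to sampling the crossover point
process — and it vectorizes over lines, which is what makes 50,000-line
calibration runs cheap.

Two design points deserve emphasis:

* **No interference in simulation, Kosambi in estimation.** Simulating
  without interference gives sharp closed-form oracles (the
  Haldane–Waddington fixation limit `R = 2r/(1+2r)`, and an exact
  ten-state two-locus selfing chain evaluated in the test suite for
  finite generation numbers). The mapping stage still converts
  recombination fractions with the Kosambi function, as maps in this
  field are conventionally reported. Tests compare recombination
  fractions, where the mapping-function choice cancels.
* **Residual heterozygosity is simulated faithfully**, not forced to
  fixation: F5-derived lines retain `(1/2)^4 ≈ 6.25%` heterozygous calls
  per locus, and the QC/linkage stages are responsible for handling them
  (two-point estimation simply excludes non-homozygous calls). Whether
  heterozygous calls should instead be treated as missing upstream is a
  policy question the package deliberately leaves to QC.

The default model genome (`default_genome()`) has 5 chromosomes of
40–60 Mb and 100–130 cM, each with one low-recombination middle block
(slope ratio 1:10 against the arms) and 500 uniformly placed markers — a
desk-scale mimic of a small plant genome with pericentromeric
heterochromatin. One integer seed governs all sampling.

`corrupt_assembly()` plants disjoint, well-separated marker intervals:
inversions reflect positions in place (an involution, so the planted
ledger restores them exactly); translocations append an interval to
another chromosome's end, half of them also inverted; detachments move an
interval into a named scaffold with 1-based offsets. Interval allocation
caps entry-generating errors per chromosome and forbids two blocks from
the same source landing adjacently on one target, so that planted entries
remain individually detectable. The generator verifies its own truth set
before returning: applying the planted ledger to the corrupted placement
must restore every marker's chromosome, the exact positions of unmoved
markers, and the internal order of moved blocks.

# Genotype QC and binning

Markers are filtered before lines, in that order. A marker is removed if
its missing fraction strictly exceeds 10% (a marker at exactly the
threshold survives — the cut is read literally as "greater than") or if a
chi-square test of its homozygous A:B counts against the 1:1 RIL
expectation is significant at the 1% level. The test uses 1 df, excludes
heterozygous and missing calls, and applies no continuity correction
(recorded in the report); excluding the small heterozygous class avoids
committing to a generation-specific heterozygosity expectation. Lines are
then removed at the same strict 10% missingness rule, recounted over the
surviving markers. Both filters are idempotent.

Markers with byte-identical call vectors (`MISSING` is a distinct symbol;
treating it as a wildcard would make binning order-dependent) are
collapsed to their first member before ordering and re-expanded to the
representative's map position afterwards, co-located members ordered by
marker id for determinism.

# Linkage grouping, ordering, distances

Two-point statistics for all marker pairs are computed by crossproducts
of a +1/−1/0 encoding (homozygous reference / homozygous alternate /
other), giving recombinant and informative counts in two BLAS calls. The
recombinant-line fraction is inverted to a meiotic fraction with the
selfing-RIL limit `r = R/(2(1−R))`; the F5-vs-F∞ bias of that limit is
smaller than estimation noise at the population sizes simulated here, and
the choice is recorded rather than corrected. The LOD is the standard
two-point likelihood ratio `k·log10(R/0.5) + (n−k)·log10((1−R)/0.5)`.

Groups are connected components of the graph with edges at LOD ≥ 11.
Within a group, ordering minimizes the sum of adjacent `r`: a minimum
spanning tree on the `r`-weighted complete graph seeds an initial order
(depth-first sweep from one end of the tree's diameter), refined by
segment-reversal (2-opt) until no improving move remains. The 2-opt
window is unbounded by default: experiments during development showed
that sparse groups (tens of markers) can need reversals spanning a third
of the group, which a narrow window never finds, while the unbounded pass
costs well under a second even at 400 markers because few improving moves
remain after MST seeding. A window cap remains available for very large
groups. Ties are broken deterministically, and a group's orientation is
fixed by positive rank correlation with physical position when a
placement is supplied (else lexicographically), so runs are reproducible.

Positions are cumulative Kosambi distances, `d = 25·ln((1+2r)/(1−2r))`
cM, with fractions clamped just below 0.5 before evaluation.

# Concordance analysis

`detect_corrections()` compares one linkage map against one placement,
chromosome by chromosome, after a majority-vote assignment of groups to
chromosomes (ties and double-claims are flagged, not guessed).

* Markers whose group is not the chromosome's own form maximal same-group
  runs → `MOVE` entries toward the group's chromosome (single-marker
  moves are allowed; a run whose internal genetic order is reversed is
  `MOVE_AND_REORIENT`). Single-marker re-orientations are impossible by
  definition — the orientation of a point is undefined — so single-marker
  rows are always moves.
* Native markers are segmented by the sign pattern of adjacent genetic
  differences: maximal strictly-decreasing runs are inversion candidates,
  and the non-decreasing remainder is split further at forward jumps
  larger than `jump_cM` (default 10 cM) so that a displaced block is not
  silently absorbed into a neighbor's run. A decreasing run qualifies as
  `REORIENT` only when its cM interval fits between its neighbors' — a
  genuine in-place inversion does; the decreasing *junction* between two
  displaced runs does not, and a two-marker junction instead donates its
  boundary markers to whichever neighboring runs they continue
  monotonically. A non-decreasing run flanked on both sides whose cM
  interval does not lie between its physical neighbors' is
  `REPOSITION_WITHIN`. Runs touching a chromosome end have only one
  physical neighbor and are exempt from the displacement test (the
  plural reading of "between its neighbors"); this is also what makes
  detect-after-apply converge, since applied moves append at chromosome
  ends.
* Lone outliers — interior markers whose removal leaves locally monotone,
  monotone-context neighbors — are reported as singletons, never as
  corrections. A genuine two-marker inversion is indistinguishable from
  such noise at marker resolution; with the default `min_run = 2` the
  flank-consistency rule separates the two cases.
* A chromosome whose overall cM-vs-bp rank correlation is negative is
  flagged as whole-chromosome orientation and analysed in the reversed
  sense, rather than drowned in per-segment noise.
* More than 5 entries on one chromosome collapse to a single `COMPLEX`
  entry spanning them — a declared reporting convention for chromosomes
  needing wholesale re-assembly.

Two single-population ledgers merge with `merge_support()`: same action,
same chromosome, overlapping spans → one `BOTH` entry over the
intersection; everything else keeps its single-population label.

`apply_corrections()` reflects `REORIENT` spans in place and appends
moved spans past the target chromosome's current end (with only a
placement in hand there is no genetic information to interpolate an
insertion point; the AGP layout records full provenance, and a second
detection pass on the result is empty). Overlapping entries are rejected
before any mutation; `COMPLEX` entries are skipped with a warning.

# Scaffold anchoring

A scaffold is anchored to the chromosome assigned to its markers' linkage
group; markers on different groups, or populations disagreeing on the
chromosome, flag the scaffold instead. The genetic position is the median
cM of its markers, kept per population — maps have different scales, so no
cross-population averaging. Orientation is the sign of the offset-vs-cM
rank correlation and requires at least two markers with distinct cM and
distinct offsets; otherwise `UNKNOWN`. The summary counts each scaffold
once regardless of how many SNPs it carries.

# Marey maps and heterochromatin

`build_marey()` pairs each shared marker's cM with its bp, flips the map
if the rank correlation is negative, and drops residual non-monotone
points by retaining a longest non-decreasing subsequence (the dropped
count and positions localize unrepaired assembly errors).

"The region between the two inflection points" is operationalized as the
breakpoints of a continuous segmented least-squares fit of cM on bp,
using the hinge basis `{1, x, (x−b1)+, (x−b2)+}`. Three-segment fits
(interior block) and two-segment fits (block abutting an end, reported
with start 0) are both searched; breakpoints move on a coarse grid of at
most 80 marker positions and are then refined over all marker positions
near the coarse optimum — this agrees with the exhaustive
all-marker-pairs grid to marker resolution at a fraction of the cost.
Segments must span at least 2 Mb (suppresses spurious micro-segments). A
candidate qualifies as heterochromatin only if the low segment's slope is
at most 0.25 of the *smaller* flanking slope; the smaller (not the mean)
is used because a block abutting the chromosome start can otherwise be
re-described as an interior block with a redundant low-slope left flank
that passes a mean-based test. Among qualifying candidates the minimum
residual sum of squares wins; if none qualifies the chromosome is
reported all-euchromatic. Breakpoints are reported at 0.1 Mb resolution,
and exactly one heterochromatic interval per chromosome is fitted —
multi-interval detection is out of scope.

Partition totals use continuous coordinates (interval length
`end − start`), matching how such tables are printed in Mb; the summary
accepts a declared assembly total that may exceed the sum of interval
bounds, since assemblies count sequence beyond the last delimited
interval.

# Marker liftover

`insilico_pcr()` matches primers exactly — no gaps, no mismatches; IUPAC
ambiguity codes in the genome count as mismatches — on both strands and
returns every product within 10 kb, coordinates 1-based inclusive over
the primer outer ends. `match_source()` emulates a high-identity
megablast: exact 50-mer seeds tiled along the source, ungapped extension
along the seed diagonal, hits kept at ≥ 99% identity over ≥ 95% of the
source length (identity and coverage are deliberately separate
thresholds), overlapping hits merged to the best, and seed words with
over 1,000 occurrences discarded as low-complexity (a deterministic stand
against repetitive seeds in place of a composition filter). An SSR is
placed only where a PCR product, an overlapping source hit, the exact
expected amplicon length (tolerance 0 by default, config-exposed) and at
least five tandem motif copies between the primer inner ends coincide;
one qualifying region is `UNAMBIGUOUS`, several are `AMBIGUOUS`, none is
`UNPLACED` with the failed criterion recorded. SNPs are placed by their
concatenated flanks with one wildcard position, whose genomic coordinate
becomes the position.

# What the tests show — and what they do not

The synthetic populations reproduce the meiotic sampling structure of
selfing-derived RILs (verified against an exact two-locus chain), but not
genotyping artifacts of real array data: allele-calling clusters, batch
effects, paralog cross-hybridization, or segregation distortion driven by
linked viability loci (the simulator's distortion hook resamples carriers
marker-wise, a deliberately crude stand-in). Planted assembly errors are
clean marker-interval events; real misjoins can fall between markers,
where marker-resolution detection necessarily reports the flanking
interval. Passing the recovery suite therefore demonstrates algorithmic
correctness under the stated model, not performance on any particular
real assembly.

Problem sizes used by the test and acceptance runs — chosen as the
smallest sizes at which the statistical checks have sharp expectations —
are: 1,000-line populations with 200 markers for recombination-fraction
calibration (the per-pair z-scores against the exact F5 chain are
required to behave like standard normal draws: at least 98.5% within 3 SE
and none beyond 5); the 5-chromosome, 2,500-marker default genome with 8
inversions, 4 translocations and 10 detached scaffolds for recovery
(required exact on marker boundaries, 100% of scaffolds to their true
chromosome); 50 seeded single-chromosome genomes at 500 markers with
0.5 cM positional noise for chromatin breakpoints (RMSE ≤ 1 Mb);
sub-100-kb genomes for exhaustive liftover equivalence; and 30 SSR plus
20 SNP planted loci (five of each duplicated) for status assignment.

# Numerical and degenerate-input conventions

Coordinates are 1-based inclusive bp throughout; conversion to 0-based
half-open happens only at the BED boundary. Genotype symbols are fixed to
`{A, B, H, -}` on disk; vendor codings must be pre-mapped. Mb table
values are stored as bp by ×10⁶ rounding. Kosambi input is clamped below
0.5; zero-length groups map to a single locus at 0 cM; an all-missing
population is an explicit error rather than an empty result; ordering and
orientation ties break lexicographically. The fixture loader verifies
file digests before parsing, and every pipeline run writes a manifest
with its seed, configuration, stage timings and output digests —
identical seeds produce byte-identical artifacts.

# Known limitations

Ordering is a heuristic (MST seeding plus 2-opt): optimality is verified
exhaustively only for small groups, and multipoint likelihood ordering is
out of scope. Breakpoints are reported at marker resolution — no
sequence-level refinement, optical maps or Hi-C. The two-population
support model is a pairwise merge, not a consensus map. Exactly one
heterochromatic interval per chromosome is fitted. The liftover stage
performs no gapped alignment, so indel-bearing loci will fail the
identity threshold rather than align around the gap.
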