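---
title: "Methods: A+T-rich centromere analytics with cenATkit"
author: "cenATkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: A+T-rich centromere analytics with cenATkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cenATkit)
```

## The problem this package addresses

Regional centromeres in many yeasts, fungi and animals are conspicuously
A+T rich relative to their genomes, yet their sequences diverge rapidly
and share no obvious motif. Centromere-replacement experiments in fission
yeast — where a candidate sequence is placed next to a native centromere
and the native centromeric DNA is then deleted with a site-specific
recombinase — make this quantitative: candidate function can be scored by
the recovery of deletion clones relative to an empty-vector control and by
CENP-A^Cnp1^ chromatin immunoprecipitation. The emerging picture is a
composition threshold: sequences above roughly 0.747 A+T act like native
centromeric DNA, a 0.71 A+T sequence forms unstable centromeres, and less
A+T-rich DNA is inert, provided the candidate exceeds about 4.2 kb.
Across species, the degree of centromeric A+T enrichment scales negatively
with genome size — a surrogate for the inverse of effective population
size — as expected if centromeric base composition sits at a
mutation–selection balance.

cenATkit implements the computational layer of such a study end to end:
sequence-composition analytics, construction and mutagenesis of candidate
sequences, ChIP enrichment quantitation with marker-based read
discrimination, replacement-assay statistics with zero-event confidence
bounds, the cross-species scaling regression, and seeded simulators for
every input class so the whole pipeline is testable without external data.

## Composition analytics

`atFraction()` is the basic statistic, `(A + T) / length`, computed from
integer base counts. `windowedAT()` profiles it in windows; the default is
tiled, non-overlapping windows (window = step), because per-kilobase
figures quoted for candidate sequences are most naturally read as tiled
values, and a trailing partial window is dropped so every value averages
the same number of bases. Overlapping windows remain available through the
`step` argument.

`findATRuns()` reports maximal homopolymer runs of a single base, A or T,
of at least `minLen` bases (default 3, i.e. "longer than 2 bp"). Runs are
per-base homopolymers, not mixed A/T tracts: `ATATAT` contains no run.
A `mixed = TRUE` flag pools A and T for sensitivity analyses, since the
distinction matters for hypotheses about nucleosome exclusion by poly(dA:dT)
tracts.

`classifyCompetence()` encodes the empirical activity thresholds:

| call        | condition (defaults)            |
|-------------|---------------------------------|
| `too_short` | length < 4000 bp                |
| `active`    | A+T ≥ 0.747                     |
| `unstable`  | 0.71 ≤ A+T < 0.747              |
| `inactive`  | A+T < 0.71                      |

The length floor defaults to 4000 bp, the midpoint band between the
shortest construct observed to be stable (4.17 kb) and the longest
observed to be unstable (3.59 kb); both thresholds are configuration, not
constants, and malformed (non-monotone) threshold sets are rejected.

Residues are normalized to upper case. Strict mode (default) rejects any
residue outside A/C/G/T, naming the offending position. An opt-in
(`ambig = "gc"`) resolves IUPAC codes for composition purposes: `W`
(A or T) counts on the A/T side, every other ambiguity code counts as
G/C-equivalent — the conservative choice when the question is whether a
sequence is A+T rich *enough*.

Coordinates are 1-based closed `IRanges` throughout the package, the
Bioconductor convention; 0-based half-open coordinates appear only in
interchange formats (bedGraph, the placement TSV dialect, marker TSV/BED).

## Candidate design

`concatemerize()` tandemly repeats a unit with no linker bases; five and
seven copies of an 889 bp unit give 4445 and 6223 bp, matching the
pentamer/heptamer constructs scored in the replacement assay.

`buildInterleaved()` alternates fixed-width segments from two pools (high
A+T "CDEII-like" segments and moderate-A+T gene-backbone segments, in the
published design: 20 bp at ~0.94 and ~0.55 A+T, to ~5.9 kb). The output is
truncated at the last whole segment rather than padded, so the overall
composition is exactly the mean of the chosen segments' compositions. Note
that 0.94 is not attainable on an individual 20 bp segment (18.8 bases);
`genSegmentPool()` therefore cuts pools from one longer exact-composition
sequence, so the pool *mean* is on target and per-segment values vary
binomially around it. The resulting 5.9 kb design has an expected overall
A+T of about 0.746 — consistent with the printed 0.74 once rounded.

`introduceMarkers()` places one short deletion (default 4 bp) per full
1 kb block, jittered uniformly around the block centre (default jitter
spacing/4). Jitter large enough to let adjacent deletions collide
(`spacing − 2·jitter < delLen`) is rejected, and deletions are kept at
least `delLen` from the sequence ends. The `MarkerSet` records positions in
unmodified coordinates together with the deleted strings, so
`revertMarkers()` restores the input exactly — the invariant the tests
enforce across seeds.

The two mutagenesis schemes mirror the two ways of asking whether A/T
*runs* or *bulk composition* carry centromere function:

* `disruptRuns()` breaks every run longer than `maxRun` (default 2) by
  substituting G or C at every `(maxRun + 1)`-th run position — the greedy
  left-to-right scheme, chosen because it is deterministic in its site
  choice (randomness only in G vs C) and provably minimal in substitution
  count for that scan order.
* `reduceATPreservingRuns()` leaves every run longer than `maxRun`
  byte-identical and lowers composition only through substitutions outside
  those runs, landing within `1/length` of the target; unattainable
  targets produce an error that reports the achievable floor.

Exact published mutant sequences are not distributed with the package;
these operations implement the general schemes, with seeds making any
specific instance reproducible.

## ChIP enrichment

Read placements enter either as text SAM (primary mapped records only;
alignment itself is out of scope — the package consumes placements) or as
the canonical tabular dialect `reference, start, end[, sequence]` with
0-based half-open coordinates, which keeps unit tests free of binary
format coupling. `coverageTrack()` computes per-base depth with
`IRanges::coverage()`; its integral always equals the summed read lengths,
and placements beyond the reference are an error, not a clip.

`normalizeToReference()` implements the study's normalization: the factor
is the *average read count* over the centromeres of chromosomes 1 and 3
(counts, not coverage means — the counts may be supplied directly or
computed from placements on those intervals). Raw depth is retained so
normalization is losslessly invertible.

`markerIndex()` and `assignReads()` discriminate reads from the engineered
construct versus near-identical native DNA. Each deletion contributes an
experimental junction word (`2·flank` bases spanning the junction;
default flank 10 bp) and the matched native word (deletion + flanks).
Index construction fails on any collision — duplicate words, an
experimental word present in the native sequence, or a native word present
in the marked sequence — because a colliding index could silently
misassign. Reads with at least one experimental word and no native word
are `experimental`; the converse, `native`; everything else `ambiguous`,
with a reason code (`no_marker_word`, `both_words`, or `too_short` for
reads shorter than a junction word, which can never be assigned). Most
reads on a 1-per-kb marker grid are structurally ambiguous; the assays of
interest use only the unambiguous classes, whose mixture proportion is an
unbiased estimate of the underlying mixture (verified by simulation).

`bindingATRegression()` tiles the sequence into 180 bp segments (trailing
partial segment dropped; the tiling offset is fixed at zero) and regresses
per-segment binding on per-segment A+T by ordinary least squares with a
two-sided slope test. "Binding" per segment is not uniquely defined by the
source analyses, so the default is mean normalized depth with a
`read_count` mode available; whether normalized or raw depth enters is a
flag, and both choices are echoed in the returned metadata. Fewer than
three segments is an error (the regression is undefined), a response with
zero variance returns slope 0 and R² 0, and a predictor with zero
variance is an error.

## Assay statistics

`recoveryEfficiency()` is the two-arm accounting of the replacement
assay: confirmed-swap recovery in the integrase arm
(`viable × fracUraMinus × fracSwapped`) as a proportion of viable cells in
the empty-vector arm. Values above 1 are legitimate — cells that complete
the swap to a shorter centromere can outgrow the control — and are
returned unclamped.

`zeroEventUpperBound(trials, confidence)` is the exact zero-event bound:
the largest per-trial probability `p*` consistent with seeing no events,
solving `(1 − p*)^trials = 1 − confidence`. It is continuous in `trials`,
which matters because lineage-division counts are non-integer. With 233
observed mitoses and 99% confidence the bound is 0.0196 per division.

`lineageDivisions()` encodes the mutation-accumulation accounting: picking
one random colony per streak round propagates only that colony's founding
lineage, `log2(colonySize)` informative divisions per line per round, so
the effective trial count is `lines × rounds × log2(colonySize)` — about
4450.7 for 20 lines, 10 rounds and colonies of 5 × 10⁶. This accounting
(rather than total colony divisions) is the one consistent with the
published ~0.1% repositioning bound, and it is isolated behind the
`LineageModel` interface so an alternative accounting can be swapped in.
`movementRateBound()` composes the two; `rateBoundPercent()` reports it on
the percent scale.

## Evolutionary scaling

`fitScaling()` regresses relative centromeric A+T — centromere minus
genome, in percentage points — on the logarithm of genome size in bp,
plain OLS with no phylogenetic correction (deliberately; the analysis it
mirrors used none, and adding one is a non-goal). Two conventions were
genuinely open and were fixed as follows:

* **Log base 10.** The source analysis says only "logarithm of the genome
  size"; base 10 over genome sizes in bp is the conventional display scale
  and is the package default. The base is an argument, and changing it
  rescales the slope by exactly `ln(10)` while leaving R², F and p
  untouched (asserted numerically in the tests), so nothing downstream
  depends on the choice.
* **Percentage points, not fractions.** A slope near −8 per decade of
  genome size over a ~2.4-decade range implies a ~19-point span of the
  response, which is only consistent with the dependent variable measured
  in percentage points (0–100). The TSV schema makes this explicit
  (`genome_at_pct`, `centromere_at_pct`).

The returned `ScalingFit` carries slope, intercept, slope SE, t, p, R²,
adjusted R², and F on (1, n−2) df, with validity checks tying them
together (`F = t²`, the adjusted-R² identity). `cladeSubsetFit()` refits
within one clade and returns an explicit `insufficient_species` outcome
below n = 3 instead of an error, since small clades (a six-species
green-plant set, say) failing to reject the null is itself a result.
Duplicate species names are rejected at load.

## Synthetic data: what it emulates and what it does not

All generators are pure functions of their parameter record; the record
(`truth`) regenerates the output bit for bit (`regenerateFromTruth()`),
and seeded calls never disturb the caller's RNG stream.

`genSequence()` draws from a two-state hidden process — state W emits A/T,
state S emits G/C — whose stationary W weight is the target composition.
`runIntensity` multiplies the expected state run length at fixed
composition and sets the within-state base persistence
`runIntensity/(runIntensity + 1)`, so homopolymer run structure and bulk
composition can be varied independently, which is exactly the contrast the
two mutagenesis schemes probe. After emission, an exact-count correction
flips randomly chosen state assignments so the realized A+T equals
`round(length × target)/length`; this perturbs run structure negligibly
and makes composition guarantees deterministic rather than probabilistic.

`genChipExperiment()` draws read starts with density proportional to a
fold-enrichment layout on the experimental sequence, mixes in native-origin
reads at a set weight, and applies i.i.d. substitution errors. It does
*not* model GC bias in library preparation, realistic error profiles,
duplicate reads, or mapping ambiguity; passing tests therefore demonstrate
correctness of the quantitation given placements, not robustness to
alignment artefacts.

`genSpeciesTable()` simulates the scaling law with uniform log10 genome
sizes. Its defaults are the study-scale conditions: n = 43 species, slope
−7.831, genome sizes 10⁷–3×10⁹ bp, a 55% genome-A+T baseline, intercept
74 (placing relative enrichment in the observed 0–30 point range), and
noise σ = 8.5 points, sized so the regression explains roughly 30% of the
variance. Derived centromere A+T is clamped to the representable 0–100
range; clamps are counted in the truth record and are vanishingly rare
under the defaults. The generator does not emulate phylogenetic
autocorrelation or clade-specific outliers.

`genAssayOutcome()` samples the integrase arm (Poisson viable count,
binomial auxotroph and swap counts) scaled so the expected recovery equals
the requested truth exactly — including truths above 1 — while the control
arm reports its viable count at expectation, because a stochastic
denominator would bias the expectation of the ratio.

## Numerical choices and degenerate inputs

* Zero-event bounds use the closed form, verified against a bisection
  oracle to 10⁻⁹; confidence outside (0, 1) or non-positive trials error.
* Windows larger than the sequence, empty pools, empty marker sets for
  index construction, regressions with under 3 points or a constant
  predictor, and non-positive normalization counts all raise immediate,
  specific errors rather than propagating NaN.
* Ties in `selectATWindows()` rankings break by start coordinate.
* `introduceMarkers()` with `delLen = 0` is an explicit no-op.
* All stochastic operations take a `seed` and are bit-reproducible;
  sub-seeds for multi-replicate runs are derived arithmetically and kept
  below 2³¹.

## Problem sizes in the test suite

The shipped tests run the full pipeline at reduced but non-trivial scale,
chosen as comfortable interactive sizes: candidate sequences of 3–10 kb,
ChIP simulations of a few thousand reads, 500 replicate species tables for
the slope-recovery study, 1000 replicates for the regression type-I-error
check, and 10⁴ fuzzed sequences (60–160 bp) for the mutagenesis
postconditions. The statistical assertions use 3-standard-error bands
around their Monte Carlo truths throughout.

## Known limitations

* Percent-identity comparisons against real genomes, peak calling, and
  alignment are out of scope; the package consumes read placements.
* The published per-sequence ChIP regressions (R² values for specific
  constructs) depend on deposited sequencing data and are not reproduced
  here; the package instead verifies the regression machinery by parameter
  recovery and nominal type-I error on synthetic data.
* The competence classifier is a threshold summary of a small number of
  assayed sequences; the band edges carry experimental uncertainty that
  the classifier interface deliberately exposes as configuration.
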