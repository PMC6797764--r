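---
title: "Scoring risk-assessment behavior and its molecular correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring risk-assessment behavior and its molecular correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethorisk)
```

## The problem

Rodent anxiety assays — the elevated plus maze (EPM), the dark/light
transfer box (DL) and the open field (OF) — measure the conflict between
exploration and safety. Classic readouts (time on the open arms, time in
the light compartment) conflate two different processes: the animal's
willingness to expose itself and the *risk assessment* it performs before
committing. ethorisk separates the two by partitioning each arena into
zones with behavioral roles and scoring how occupancy distributes across
them, then links those behavioral traits to transcriptome structure through
a weighted co-expression network and to protein-interaction topology
through hub and dense-subnetwork scoring.

## Arena geometry and zones

`build_zonemap()` constructs a planar partition per apparatus, using the
standard dimensions:

* **EPM** — 5 × 5 cm center, two open and two closed arms of 30.5 × 5 cm,
  arena-centered coordinates with the open arms on the x axis. Each open
  arm is split into an *entry zone* (proximal band of depth `entry_depth`)
  and the remaining distal arm.
* **DL** — 14 × 27 cm dark compartment joined to a 30 × 27 cm light
  compartment; the light side is split into an entry band adjacent to the
  divider and the remaining light core. The entry band spans the divider's
  full 27 cm width, the simplest faithful reading of the apparatus (the
  passage position is not standardized).
* **OF** — 50 × 50 cm square with a 25 × 25 cm center region.

The entry-zone depth defaults to 5 cm, equal to the arm width; there is no
canonical published value, so it is a configurable parameter rather than a
constant. Containment is boundary-inclusive with first-match priority in
the zone list (the center square therefore wins ties against arms, so the
5 × 5 cm center belongs to the risk-assessment zone rather than to any
arm). Points inside the footprint missed by every zone polygon fall back
to the nearest zone by Euclidean distance; points off the footprint are
flagged `off_arena` rather than erroring, since tracker glitches should
surface in dwell tables, not crash a pipeline.

## Behavioral readouts

With `i` the center dwell time, `ii` the summed open-arm entry-zone time
and `iii` the summed distal open-arm time, the EPM risk-assessment index
is

$$\mathrm{RA}_{\mathrm{EPM}} = \frac{i + ii}{i + ii + iii},$$

the fraction of open-area time spent assessing rather than committed.
Because `ii` and `iii` are stored as two-arm totals, writing the per-arm
quantities with a factor of two is numerically identical; the totals form
is the one implemented. In the DL test the analogous index is
`entry / (entry + light_core)`. Both are undefined — reported `NA`, never
silently zero — when the animal never samples the open/light area, which
happens for extreme avoiders.

Risk *taking* in the DL box is indexed by the hidden–entry–hidden (HEH)
pattern: among all hidden-to-entry excursions, the fraction that retreats
straight back to the dark compartment. The denominator counts consecutive
run pairs (hidden, entry) in the run-length-compressed zone sequence; the
numerator counts those completed to (hidden, entry, hidden) triples. Lower
HEH means the animal presses on into the light more often.

Stretch-attend postures (SAP) are detected as maximal intervals with body
elongation (nose to tail-base distance over the trial median) at least
1.2 while centroid speed stays at or below 2 cm/s, lasting at least
0.5 s. These thresholds are detector defaults, not published constants:
commercial trackers do not disclose their SAP parameterization, so the
detector is a stand-in validated on constructed fixtures and synthetic
bouts. The relative SAP frequency is the fraction of events whose midpoint
falls in a risk-assessment zone (center or entry). Protected head dips are
maximal intervals with the nose beyond the maze footprint while the
centroid remains in a protected zone (center, entry or closed arm); a
pre-annotated event table is accepted as an alternative input for users
who score dips manually.

Entries are counted on run starts, excluding the run that begins the trial
(initial placement is not an entry), mirroring tracker-software
convention. All dwell tables satisfy a conservation invariant: zone times
plus `off_arena` sum to the trial duration within one frame period.
Risk-assessment zone time is accumulated per trial, not per visit.

## The trajectory simulator

`simulate_trajectory()` generates synthetic tracking data from a two-level
model chosen because every readout above is a zone-occupancy statistic:

1. a **zone-level Markov chain** decides where the animal is and for how
   long. Transitions go to adjacent zones; weights on exposed zones
   (center, entry, open arm, light side) are proportional to
   `open_preference` and on sheltered zones to `1 - open_preference`.
   Mean per-visit dwell in the risk-assessment zones is
   `0.5 + 7.5 * risk_propensity` seconds, against fixed means of 4 s in
   committed exposed zones and 10 s in sheltered zones;
2. a **bounded correlated random walk** moves the animal within the
   current zone at per-frame speeds drawn from a truncated normal
   (defaults 6 ± 2 cm/s), with reflecting zone boundaries implemented by
   coordinate folding. Zone changes are straight dashes to the midpoint
   of the shared edge at the same speed process, so locomotion statistics
   are independent of the risk parameters — the design deliberately
   mirrors the dissociation between risk assessment and locomotion that
   the assays are meant to expose.

The animal starts in a sheltered zone (a closed arm, the dark
compartment, the OF periphery). A consequence worth stating: with
`open_preference = 0` the chain never leaves shelter, so the risk indices
are undefined for such animals — the degenerate case the `NA` flags exist
for. Trial lengths default to the standard protocol (300 s for EPM and
DL, 600 s for OF) at 25 Hz.

Body points place the nose and tail-base half a body length (default
8 cm) fore and aft along the instantaneous heading. Stretch-attend bouts
arrive as an alternating renewal process (default 6 bouts/min, 0.6–1.2 s
long) during which speed drops near zero and the nose offset is elongated
1.5-fold; wall geometry clips some bouts, so detected counts land in a
realistic 3–10 per trial. Head-dip bouts (default 3/min) push the nose
1 cm past the arm's side edge while the animal is in an entry zone.

Every generator is a pure function of its parameters and seed:
`.Random.seed` is saved and restored, and cohort members get per-animal
seeds derived deterministically from the master seed.

What the simulator does **not** emulate: thigmotaxis gradients within
zones, freezing and grooming bouts, posture dynamics beyond the
elongation caricature, habituation across the trial, or inter-animal
variability in speed. Tests passing on this generator demonstrate that
the *scoring and inference machinery* is correct and sensitive, not that
any particular biological effect size is realistic.

## Group comparison

`compare_groups()` implements the adaptive routing used widely in
behavioral work: Shapiro–Wilk normality per group and Levene's test
(mean-centered, the classic form) for variance homogeneity, both at
α = 0.05 (configurable); two normal groups with equal variances get
Student's *t*, unequal variances Welch's *t*, and any non-normal group
routes to the Mann–Whitney U test. Normality gates before variance
because a rank test is the fallback for either failure. Constant groups
are treated as non-normal (the Shapiro statistic is undefined there);
two identical constant groups are an error. The Mann–Whitney route uses
exact enumeration up to n = 8 per group without ties and the
tie-corrected normal approximation otherwise. Results carry mean ± SEM
and the routing diagnostics so the choice is auditable. Monte-Carlo
checks in the test suite show the procedure holds its nominal type-I
error within Monte-Carlo error for Gaussian data and reaches ≥ 60% power
at a 1 SD shift with 12 animals per group — the cohort sizes typical of
these assays.

`bh_fdr()` is the Benjamini–Hochberg step-up. Across behavioral metrics
it is off by default (`compare_profiles(fdr = FALSE)`): the convention
followed is to correct within correlation families (module–trait tables)
and report per-metric p-values otherwise; the switch exists for users who
prefer otherwise.

## Co-expression network

The expression stage reimplements the standard signed weighted
co-expression workflow:

* genes kept when expressed (> 0) in **strictly more than** 10 samples
  (the filter is deliberately strict-greater; a gene present in exactly
  10 samples is dropped);
* **biweight midcorrelation** between gene rows: observations weighted by
  `(1 - u^2)^2` for `|u| < 1`, `u = (x - median) / (9 mad)` with unscaled
  MAD; genes with zero MAD fall back to Pearson with a warning, and the
  robust/fallback vectors mix transparently for cross pairs;
* **signed adjacency** `((1 + cor)/2)^beta` with β = 10, the value
  selected by the scale-free topology criterion in striatal data of this
  kind (`scale_free_fit()` reports the signed log–log R² if one wants to
  re-derive β on other data);
* **topological overlap** `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 -
  a_ij)` and clustering of `1 - TOM` by average linkage;
* **module detection** by a static cut at height 0.99 followed by a
  minimum-size gate (30 genes), eigengene merging at dissimilarity 0.30,
  and a module-membership cleanup that returns genes with kME below 0.3
  to grey. The full dynamic hybrid tree-cut heuristic is replaced by this
  simpler, swappable procedure: the properties exercised here (planted
  module recovery, trait correlation) do not depend on the exact cutting
  heuristic, and the static cut is transparent and deterministic. The
  merge threshold and the size gate are surfaced as two separate knobs
  because "minimum height of 30" conflates them in common usage;
* the **module eigengene** is the unit-norm first right singular vector
  of the row-standardized module submatrix, sign-aligned to correlate
  positively with the module's average standardized expression (so it
  *tracks* module expression; negating every gene negates the ME);
  module–trait association is Pearson r with two-sided p and BH-FDR
  within each trait across modules; module membership and gene
  significance are the usual per-gene correlations, GS taken in absolute
  value.

Abundance matrices are log2(x + 1)-transformed before correlation by
default (FPKM-like inputs are heavy-tailed); the transform is off for
data already on a log-like scale, including the package's own simulator
output. Traits may be per-sample measurements, per-group behavioral means
attached to expression samples, or genotype indicators — the latter two
are the realistic designs when sequenced animals were not behaviorally
tested, and both are plain columns in the trait table.

The expression simulator plants modules via per-sample latent factors
with positive loadings in [0.8, 1.2] and gene noise of standard deviation
`noise_sd`; the trait is `sum(r_m f_m) + sqrt(1 - sum(r_m^2)) ε`, giving
the requested expected correlations exactly. With module size 50, 50
samples and `noise_sd = 0.8` (within-module correlation ≈ 0.6), the full
pipeline recovers labels at adjusted Rand index ≈ 0.95 and the planted
trait correlation within ±0.15 on average — the regime the acceptance
checks exercise.

## Protein-interaction stage

Edge lists with confidence scores are filtered at ≥ 0.700 (inclusive, the
"high confidence" convention of the usual source databases), deduplicated
keeping maximum confidence, and loaded as an undirected simple graph.
Hubs are scored by degree and unnormalized betweenness on the unweighted
skeleton (no published analysis of this kind weights path lengths by
confidence). Dense subnetworks use the seeded density-based procedure of
the MCODE family with its stock parameters: node weight = neighborhood
highest-k-core number × that core's density, greedy expansion at node
score cutoff 0.2, post-filter requiring a 2-core, score = density × size,
and no haircut/fluff refinements. Clusters are node-disjoint by
construction.

## Numerical choices and degenerate inputs

* Undefined ratios (`0/0` risk indices, HEH with no hidden-entry pair,
  SAP fraction with no events) return `NA`; group statistics drop them
  with a reported count.
* Zone label smoothing is a running median over integer zone codes,
  default off (window 1).
* Ties at zone boundaries resolve by zone-list order, documented per
  arena; mirrored points land in mirrored zones of the same role.
* Correlations are clamped to [-1, 1] against floating-point overshoot;
  TOM to [0, 1]. The TOM of an edgeless graph is the identity.
* `scale_free_fit()` refuses constant-connectivity networks (the log–log
  regression is undefined there) and networks under 20 nodes.
* Tree cutting is deterministic; the whole expression stage has no random
  initialization, so rerunning on the same matrix is bit-identical.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on synthetic
data at desk scale, chosen to mirror the study designs these assays use:
behavioral cohorts of 12 animals per group at 5-minute trials and 25 Hz,
100–200 Monte-Carlo cohort repetitions, 2000 null simulations for test
calibration at n = 20 per group, planted-module matrices of 50-gene
modules across 50 samples repeated over 20–50 seeds, and interaction
graphs of a few dozen nodes with planted cliques. Published headline
numbers that depend on a specific sequencing dataset or database release
(module counts and sizes, specific hub genes) are out of scope by design;
the checks validate formulas, oracle equivalence, calibration and
parameter recovery instead.

## Known limitations

* The zone-transition chain has no memory beyond the current zone, so
  sequence statistics richer than HEH (e.g. multi-visit patterns) are not
  calibrated.
* SAP and head-dip detection are threshold detectors on two body points;
  with real pose-estimation output one would validate thresholds against
  manual scoring before trusting absolute counts (relative group
  comparisons are more robust).
* The static-cut module detector can split one true module across two
  branches on borderline data where the dynamic hybrid cut would not;
  the eigengene merge step recovers most such splits.
* Betweenness is exact, not sampled; on graphs beyond ~10^4 nodes one
  would switch to approximate algorithms before using this stage.
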