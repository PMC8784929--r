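---
title: "Methods: shipping-network reconstruction and its genomic correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shipping-network reconstruction and its genomic correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shipgen)
```

## The problem

Non-indigenous marine species spread with shipping, and anthropogenic
transport homogenizes their gene pools: regions that exchange many
ships should, all else equal, exchange more propagules and end up less
genetically differentiated. Testing that expectation needs two
reconstructions that rarely live in one toolbox — a historical
*shipping network* built from centuries of once-daily ship positions,
and *population-genomic differentiation* estimated from SNP matrices of
sampled sites — plus a principled join between them. `shipgen`
implements the full chain and a synthetic-data generator that makes
every stage testable against planted truth.

## Port-call inference

Logbook-derived archives provide at most one position per ship per day
and typically no record while a ship lies in port; the observable is
the *approach*. A position is assigned to its nearest indexed port
(great-circle distance), and a call opens when that distance is at most
the threshold `threshold_km`.

* **Distance.** Haversine on a sphere of radius 6371.0 km. The formula
  is numerically stable at the small distances that matter here
  (kilometres), unlike the spherical law of cosines, which the test
  suite uses as an independent oracle away from that regime.
* **Threshold.** Default 10 km — the primary analysis value. It is the
  single most influential tunable, so `threshold_sensitivity()`
  re-runs the reconstruction over a grid (default 5, 10, 20, 50 km);
  call counts are provably non-decreasing in the threshold.
* **Call collapse and re-entry.** Consecutive in-threshold days at the
  same port extend one call; a second call at the same port requires an
  intervening out-of-threshold day or a call elsewhere. The arrival
  date is the *first* in-threshold day, the date the approach becomes
  observable at daily resolution.
* **Ties.** Two ports exactly equidistant resolve to the
  lexicographically smallest `port_id`; the output is byte-identical
  across runs.
* **Voyage segmentation.** Ship identifiers recur across unrelated
  cruises in multi-source archives. A gap of more than `gap_days`
  (default 30) between fixes splits the record; travel events never
  span a split. The default is deliberately conservative — roughly the
  longest plausible unobserved passage for the sailing eras covered —
  and is exposed because no archive documents its id semantics well.

Travel events are consecutive distinct-port call pairs of one ship
within one voyage, directed origin → destination. A ship that leaves
the threshold and returns to the *same* port produces two calls but no
event: an event is a movement between ports by definition. Within-
*region* events (two ports, one region) are genuine shipping and are
retained; a flag in the CLI drops them for users who want pure
between-region flows.

## Temporal and spatial aggregation

Coverage in the source archives is too patchy for fine-grained
analysis, so counts are aggregated to 50-year periods — 1750–1800,
1801–1850, 1851–1900, 1901–1950, 1951–2000, both endpoint years
inclusive — and caller-supplied region labels. An event is dated by its
arrival; events outside all periods are tallied separately, never
silently dropped, and the tensor's cell sums reproduce the event counts
per period exactly (a conservation property the tests enforce). Port
visits (Fig-2f-style series) count *calls*, not distinct ships — the
natural reading at daily resolution, documented here because the
alternative is defensible too.

## Genomic statistics

Inputs are diploid biallelic SNP calls (VCF; only GT is read) with a
sample → site popmap. Non-biallelic and all-missing loci are dropped at
read time with counts logged; missing data are handled by per-locus
pairwise deletion throughout, with no imputation.

* **H~O~** — per-locus heterozygote fraction; multilocus mean weights
  loci equally (call-rate weighting is a defensible alternative; equal
  weighting is the package's documented choice).
* **H~E~** — gene diversity 2p(1−p), by default with the Nei (1978)
  small-sample factor 2n/(2n−1).
* **F~IS~** = 1 − ΣH~O~/ΣH~E~, a ratio of sums across loci, consistent
  with the multilocus F~ST~ convention and stable when individual loci
  have tiny diversity. A population monomorphic at every locus has no
  defined F~IS~ and reports `NA`, never 0.
* **Private alleles** — an allele (REF or ALT) observed in exactly one
  group, grouping by site or by region; `min_count` raises the
  presence bar from 1 copy. Both groupings are exposed because "private
  per site" and "private per range" answer different questions.
* **F~ST~** — Weir & Cockerham (1984) θ, the default pairwise estimator
  of the standard R packages for hierarchical F-statistics. Per-locus
  variance components a, b, c come from sample sizes, allele
  frequencies and observed heterozygote frequencies; the multilocus
  estimate is Σa/Σ(a+b+c). Small negative values are normal estimator
  behaviour and are not truncated. Two exact anchors pin the
  implementation: populations fixed for alternate alleles give θ = 1
  identically, and identical all-heterozygote populations give θ = 0 to
  machine precision. Every statistic is additionally checked against
  independently coded brute-force oracles to 1e−10 on randomized
  instances.

Region-level differentiation is the arithmetic mean of pairwise θ over
the site pairs spanning each region pair (within-region means are
computed analogously and flagged), with missing pairs excluded and
counted.

## Joining the two sides

Shipping intensity per unordered region pair is the mean over the
periods in a year window (default 1750–2000) of the symmetrized count
c(i→j) + c(j→i); a flag switches to the raw total (both readings of
"average intensity over the window" are defensible — the mean is
primary because it is comparable across windows of different length).
Symmetrization is forced by the genetic side: F~ST~ has no direction.
The association is Spearman's rank correlation — monotone, not linear,
is all the propagule-pressure argument predicts — with average ranks
for ties and a two-sided p from the t-approximation on n−2 degrees of
freedom. Because n is the number of region pairs (15 for six regions),
a seeded permutation p-value is available and preferable when the
t-approximation's accuracy is in doubt.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated; its defaults are fixed once and are not tuned per test.

* **Trajectories.** Ports are placed at random with a 300 km minimum
  separation (and the simulator refuses indexes with any two ports
  closer than twice the threshold, where planted calls would be
  ambiguous). Ships follow great-circle legs between random distinct
  ports at 300 km/day, one fix per day; on call days the position sits
  within `threshold − margin` of the port (margin 3 km, jitter 2 km),
  on transit days farther than `threshold + margin` from every port
  (track points that stray near a port are pushed clear). Recovery of
  the planted calls by `detect_port_calls()` is therefore exact by
  construction — which is the point: it isolates the bookkeeping
  (collapse, re-entry, segmentation, binning) as the thing under test.
* **Genotypes.** Ancestral frequencies uniform on [0.05, 0.95]; per
  population, Balding–Nichols Beta draws at divergence F; binomial
  diploid genotypes; missing mask at 5%. Defaults (2000 loci, 30
  diploids per population, F = 0.1) match the GBS scale of the SNP
  matrices this pipeline targets, and make parameter recovery a crisp
  check: multilocus θ should land within ±0.02 of F at that size, and
  within ±0.01 of zero at F = 0 (tolerances frozen after inspecting
  replicate spread at these sizes, before wiring them into tests).
* **Coupled scenario.** A symmetric integer shipping matrix S with a
  wide spread; the declared divergence target of pair (i,j) is
  F_max/(1 + c·s_ij) with s the max-scaled S and c = 4 ("strong"
  coupling: shipping spans most of the divergence range). Realization
  is by admixture: each region mixes a private Balding–Nichols
  component with one *pair-shared* component per partner, the shared
  weight proportional to c·s_ij. A purely region-level mixing matrix
  was rejected during design: it confounds a pair's divergence with
  each member's total connectivity, which destroys rank recovery of
  the planted pairwise signal. Pair-shared components keep the joint
  frequency model valid while making realized θ decrease in s_ij
  directly. The same S is emitted as a shipping tensor (and optionally
  as voyages whose detected travel events reproduce S exactly), so the
  full chain — simulate → port calls → network → F~ST~ → correlation —
  runs end-to-end from files.

What the generator deliberately does **not** emulate: position noise
correlated along a track, missing logbook days, port-index errors,
selection, linkage, isolation-by-distance unrelated to shipping, or
uneven sampling across sites. Passing tests therefore demonstrate the
correctness of the estimators and bookkeeping under the stated model,
not robustness of the historical reconstruction to archive artefacts.

## Numerical and edge-case conventions

Longitudes are accepted in [−180, 180) or [0, 360) and normalized to
the former. Duplicate same-day fixes collapse to the first parsed row.
Periods must be non-overlapping; overlap is an error, not a warning.
An empty port index, a popmap missing a VCF sample, a duplicated
port id, and a correlation with fewer than three complete pairs are
all hard errors that name the offender. Degenerate statistics (no
usable locus for a pair, monomorphic populations) propagate as `NA`
with counts reported, never as silent zeros.

## Problem sizes

The shipped test-suite and acceptance-script sizes are the package's
validation conditions: 100 randomized oracle instances up to 10
populations × 50 loci × 20 diploids; 20 replicates of the F = 0.1
recovery and 5 of the F = 0 null at 2000 × 30; 50 synthetic voyages for
planted-call recovery; 200 coupled replicates (6 regions, 2000 loci, 30
diploids per region) for the sign-recovery rate. The historical
archives themselves (hundreds of thousands of movements, a 1620-port
index) are consumed through the same CSV contracts but are not bundled;
reproducing the published period totals requires downloading those
archives and is outside the test suite's scope.

## Known limitations

Port-call inference near archipelagos or river ports inherits all the
coarseness of a 10 km disc at daily resolution; the sensitivity table
is the honest summary of that uncertainty. The Weir–Cockerham
estimator assumes the sampled populations are exchangeable draws from a
common ancestor, which shipping-mediated admixture itself violates —
the very effect under study — so θ is used descriptively, as the
field does. The region-pair correlation treats pairs as independent
observations; with n = 15 pairs sharing 6 regions they are not, which
is one more reason the permutation p-value is offered and effect
direction, not significance, is the primary read-out.
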