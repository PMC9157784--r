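---
title: "Adaptive survey design and richness estimation for aquatic plant early detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive survey design and richness estimation for aquatic plant early detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantsurv)
```

## The problem

Early detection of invasive aquatic plants in large (hundreds of hectares)
coastal areas cannot rely on exhaustive sampling: a boat crew can visit a
few dozen 100-m grid cells in a multi-day visit, out of frames of several
hundred to over a thousand cells. `plantsurv` implements the quantitative
machinery of an adaptive surveillance cycle for this setting:

1. **Design** — a probability sample over a gridded frame, spatially
   balanced so that effort spreads across the site, with per-cell
   inclusion weights encoding zone allocations or predicted richness.
2. **Survey** — rake tosses and visual scans at four stations per cell
   (simulated here by an explicit observation model).
3. **Evaluate** — incidence-based richness estimation, rarefaction and
   effort projection to ask "what fraction of the species pool did we
   detect, and what would the rest cost?".
4. **Redesign** — interpolated or habitat-modelled richness surfaces
   converted into next-year inclusion weights.

## Richness estimation

All estimation is incidence-based: each sample unit contributes a
presence/absence record per species, a species counts at most once per
unit, and units with zero detections remain in the sample size `m` (they
carry information about detectability). From the per-species incidence
frequencies we tally `Sobs`, the uniques `Q1` (frequency exactly 1) and
duplicates `Q2` (frequency exactly 2).

The Chao2 estimator extrapolates undetected richness from `Q1` and `Q2`,
with the finite-sample factor `A = (m-1)/m`:

- classic: `Sest = Sobs + A * Q1^2 / (2 * Q2)`
- bias-corrected: `Sest = Sobs + A * Q1 * (Q1 - 1) / (2 * (Q2 + 1))`

The bias-corrected form is reported by default; when the incidence
distribution is strongly heterogeneous — ICE (incidence-based coverage
estimator) coefficient of variation above 0.5 — the classic form is
reported instead, because the bias correction over-shrinks under strong
heterogeneity. Variances follow the variant-matched formulas of Chao
(1987) as used by EstimateS, and 95% intervals use the log-transform of
the undetected component `T = Sest - Sobs`, so the lower bound never
falls below `Sobs`.

A note on the ICE CV: its exact form needs `m_inf`, the number of units
containing at least one infrequent (frequency ≤ 10) species. This is
available when estimating from a matrix; when only a frequency vector is
supplied, `m_inf` defaults to `m`, a slight overestimate of the
correction factor `m_inf/(m_inf - 1)` denominator with negligible effect
at survey scale.

### Rarefaction

Sample-based rarefaction uses the exact hypergeometric expectation
`E[S_t] = sum_j (1 - C(m - s_j, t)/C(m, t))`. The default uncertainty is
an unconditional (moment-based) variance anchored to an estimated total
richness (classic Chao2 when defined), so the confidence band does not
collapse to zero at `t = m` — matching how survey species-effort curves
are reported, where the band at full effort reflects remaining
uncertainty about the pool. A seeded resampling mode is provided and is
required to agree with the analytic mean within Monte-Carlo error; the
analytic mean itself is tested against exhaustive subset enumeration on
small fixtures.

### Effort projection

The projection model assumes the number of still-undetected species
decays exponentially with added units at rate `2*Q2 / ((m-1)*Q1)`. The
additional units needed to detect a fraction `g` of the pool are

```
m_g = (m-1) * Q1 / (2 * Q2) * ln( Q0 / ((1 - g) * Sest) )
```

with **classic-variant** `Sest` and `Q0 = Sest - Sobs` even when the
reported point estimate is bias-corrected: the extrapolation is derived
from the classic estimator, and only classic inputs reproduce published
projections. Two numerical choices deserve comment:

- The leading factor carries the same finite-sample factor `A` as the
  estimator (equivalently, `(m-1)` rather than `m`). We adopted this
  after verifying that it reproduces the published 95%-detection effort
  values across all twelve reference surveys within one unit, whereas
  the uncorrected factor drifts by several units on the most
  unique-heavy survey.
- A full census (`g = 1`) is undefined under exponential decay, so
  `effort_to_census()` reports the effort at which the expected number
  of undetected species falls below `min(0.1, 0.01 * Sest)` species (the
  cap keeps census effort at or above the `g = 0.99` effort for small
  pools). Published full-census figures computed by other tools agree
  with this convention only to within a few percent; the value should be
  read as an order of magnitude.

### Endpoints and similarity

`endpoint_summary()` reports per-unit means of total, rare and
non-native richness. A species is *rare* when its incidence frequency is
strictly below `f` times the survey's total incidence; `f = 0.05` is the
standard rule and `f = 0.20` is reported alongside it as a parallel,
more inclusive threshold (the looser column is conventionally shown
without a separate definition; we interpret it as the same rule at 20%).
Design similarity uses the simplified Morisita (Morisita–Horn) index on
union-aligned incidence-frequency vectors, 0 for disjoint and 1 for
identical relative structure.

## Survey design

`build_frame()` grids an extent into square cells (100 m default,
lower-left-corner addressing, half-open intervals) with one zone label
per cell. `assign_weights()` supports three modes: uniform; fixed zone
allocation (e.g. 75% of effort to the shallow zone — implemented as
expected allocation, each zone-`z` cell weighted `alloc[z]/n_z`, with the
zone-minimum repair step as backstop); and percentile weights from a
richness surface (at/above the 90th percentile 0.6, then 0.5, 0.4, 0.3,
0.2 by decile, 0.1 below the 50th). Percentiles are computed over
unmasked cells only, as the percentage of unmasked cells with strictly
smaller value; cells deeper than the mask (6 m default, disabled for
sites nowhere near that depth) keep the floor weight or are excluded.

`spatially_balanced_sample()` implements generalized random tessellation
stratified (GRTS) sampling: quadrant-recursive addresses, an independent
random permutation of the four child quadrants at every node of the
address tree, probability-proportional-to-weight systematic selection
along the randomized address line, and reverse-hierarchical ordering of
the output so any prefix is itself spatially balanced. The proprietary
GIS tool used operationally exposes the same published algorithm; we
implement the published form as the reference. Inclusion probabilities
are capped at 1 with iterative redistribution, so an exhaustive draw
returns every cell.

The per-zone minimum ("at least ten percent of the sample units in a
zone") is enforced after selection: deficits are filled by continuing
the deficient zone's reverse-hierarchical order, and (by default) the
total is preserved by dropping tail cells from zones above their
minimum. Whether the operational allocations were enforced exactly or in
expectation is not documented; we implement expected-allocation weights
plus this repair step.

`interpolate_richness()` defaults to inverse-distance weighting (power
2): it is exact at observations, needs no fitting, and the percentile
map coarsens the surface anyway, so a monotone-reasonable interpolant
suffices for the adaptive loop. Ordinary kriging with a moment-fitted
exponential variogram is available; with identical observations no
variogram is fitted and the constant surface is returned.

## Habitat modelling

`fit_richness_forest()` regresses per-unit richness on 18 habitat
attributes (depth, littoral fraction, fetch, shoreline types and
distances, launch/marina/dock proxies) with a random forest (500 trees,
library-default split rules, seeded 80/20 train/test split; the split
protocol behind published fit tables is not documented, so we state ours
and treat the published values as structure, not targets). Reports carry
squared correlations between observed and predicted richness for train,
test and all units pooled. `importance_percent()` converts summed
impurity decreases into percents of total; `reduced_variable_selection()`
applies the ≥ 5% rule minus explicit exclusions (the two soft-shoreline
variables, which are impractical to derive for new sites). The canonical
reduced set is depth, percent littoral, maximum fetch, and distances to
boat launch and marina. `predict_surface()` feeds model predictions
(clamped at 0) into the percentile weighting.

## The synthetic landscape and what it does (not) show

Because no field data ship with the package, `generate_landscape()`,
`generate_community()` and `simulate_survey()` provide a fully seeded
synthetic pipeline whose defaults encode the study conditions the
analysis assumes:

- an 800-cell (4 km × 2 km) frame of 100-m cells, depth increasing from
  a southern shoreline to ~10 m with 0.5 m noise;
- a pool of 50 taxa, one fifth non-native; occupancy declining
  logistically with depth (midpoint 4 m, slope 1 m), zero beyond 8 m and
  small beyond 6 m; lognormal base occupancies (meanlog `log(0.08)`,
  sdlog 1.2) so surveys yield uniques and duplicates; a 1.5× occupancy
  boost within 300 m of launches/marinas; and a lognormal (sdlog 0.6)
  cell-quality multiplier shared by all species, which induces the
  positive native/non-native richness correlation observed in the field;
- four stations per cell, minimum four rake tosses per station with a
  0.3 per-toss detection probability, tossing continuing while the last
  toss yielded a station-new species; floating/free-floating/emergent
  forms get a 0.35 per-station visual detection chance. Visual rates are
  free parameters: no field estimates exist, and the visual meander is
  modelled as a per-growth-form detection bonus rather than a separate
  spatial process. Opportunistic relocation of units toward visible
  plant beds is likewise represented (optionally) as a detection
  multiplier, keeping the frame probabilistic.

Under these defaults a dispersed 60-unit survey leaves roughly 30–50% of
units without detections, consistent with first-year dispersed surveys
at deep sites. The generator does *not* emulate hydrodynamics, light
attenuation, dispersal or interannual turnover; passing tests show the
estimators and designs behave correctly under the assumed occupancy and
detection structure, not that real communities satisfy that structure.

## Desk-scale experiment sizes

The test suite and the bundled experiments use sizes chosen to make the
statistical properties visible at desk scale: rarefaction enumeration on
fixtures of up to 8 units; inclusion-frequency checks over 10,000 draws
of 10 cells from a 100-cell frame; spatial-balance sign tests over 500
paired draws; and recovery/design experiments with 200 seeded replicates
at 20 and 80 units on the 800-cell default landscape. The acceptance
script recomputes the published reference quantities from their printed
inputs, which is exact and immediate.

## Known limitations

- The full-census effort convention is an interpretation (see above);
  only its order of magnitude is meaningful.
- Rarefaction confidence bands use a moment-based unconditional
  variance; tools differ here, and exact interval reproduction across
  tools is not expected.
- The ICE CV from bare frequency vectors approximates `m_inf` by `m`.
- IDW/kriging are planar and isotropic; no shoreline-aware distances.
- The forest model's fit statistics depend on the (stated) split
  protocol; they are reproducible under the seed but not comparable
  across protocols.
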