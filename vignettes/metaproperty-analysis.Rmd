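---
title: "Metaproperty analysis of TLS scans: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaproperty analysis of TLS scans: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprop)
```

## The measurement model

A terrestrial laser scanner emits pulses over a zenith × azimuth grid
and records, for each pulse, up to two backscattered returns with their
range and relative intensity. `metaprop` represents a scan as a long
table: one row per ranged return, plus a `return_index = 0` row for
every pulse that produced no return at all. The no-return rows are
first-class data — the gap-fraction metaproperty is computed from them —
which is why the format records emitted pulses rather than only
detected points, unlike generic point-cloud formats.

Coordinates are sensor-relative: zenith 0° is vertically up, 90° is the
horizontal *optical plane* through the instrument's optical centre, and
azimuth is counterclockwise from +x seen from above. All metaproperties
are rotation-invariant, so the azimuth origin is arbitrary. The default
instrument profile (40 m maximum range, 15 mrad divergence, two returns
per pulse, sensor at 1.3 m) describes the compact 905 nm scanners this
analysis style was developed on; the sensor height is carried as
metadata only, since every computation happens in the sensor frame.

## The six metaproperties and their parameters

Three *pulse* metaproperties are population statistics over the pulses
at or above the optical plane (`pulse_band`, default [0°, 90°], a closed
interval): the mean first-return distance (m), the mean first-return
intensity (relative units in [0, 1]), and the ratio of first to second
return counts (dimensionless). Pulses without returns contribute
nothing to the means — a deliberate property: sight lines that exceed
the range limit or escape through canopy gaps leave the mean distance
unchanged rather than dragging it upward.

Three *spatial* metaproperties measure the empty space:

- **No return : pulses** over the `gap_band` (default [30°, 35°]), a
  mid-canopy view band where canopy gaps are most informative. It is a
  proportion in [0, 1] and is exactly the per-band gap fraction.
- **Optical plane area (OPA)**: first returns within
  `optical_plane_tolerance_deg` (default 0.5°) of zenith 90° are
  projected to (x, y), ordered by azimuth (ties broken by distance),
  joined into a closed polygon, and measured with the shoelace formula.
  Real scanners sample discrete zenith rows, so an exact "= 90°" test
  would select nothing; the tolerance captures the row nearest the
  horizontal. Optical-plane pulses with no return contribute no vertex,
  so the OPA of open scenes underestimates the sight-line envelope —
  an accepted bias, documented rather than interpolated away.
- **Rugosity**: first returns in the `rugosity_band` (default
  [0°, 30°]) are Delaunay-triangulated on their (x, y) projection, each
  triangle is lifted to its vertices' z values, and the metric is the
  total 3-D area over the area of the footprint. The footprint is taken
  as the convex hull of the projected points, which equals the region
  covered by the triangulation; this guarantees rugosity ≥ 1, equal to
  1 exactly for a flat surface and 1/cos θ for a plane tilted by θ —
  both of which the test suite verifies. The azimuth-ordered polygon
  was considered for the denominator and rejected: it can be smaller
  than the triangulated region, producing ratios below 1 with no
  physical meaning. No sliver-triangle filtering is applied at the hull
  boundary; on band-limited scan geometries the effect is negligible
  relative to range noise.

A metric that cannot be computed on a given scan (no returns in band,
fewer than three polygon vertices, collinear projections) is flagged
and carried as a missing value by `extract_metaproperties()`, so one
degenerate metric never aborts a batch. An infinite first:second ratio
(no second returns at all) is likewise flagged; the log-transform step
refuses flagged values rather than silently producing `log(Inf)`.

## The classification workflow

The workflow is a fixed ten-stage pipeline with three discretionary
steps, run by `run_mcm()`:

1. **Logit assessment** of each metric: a univariate logistic fit
   produces the probability curve across the metric's range; linearity
   is diagnosed as the correlation between the empirical logit of
   binned class proportions (quantile bins, 0.5 continuity correction)
   and the bin means. Logistic regression assumes the log-odds are
   linear in each predictor; a low linearity score suggests a
   transform.
2. **Separation detection**: a metric whose class ranges do not overlap
   classifies perfectly on its own, and makes the standard logistic
   maximum-likelihood estimate diverge. Non-finite values are excluded
   before the range comparison. Only separation, not its direction, is
   asserted anywhere in the package.
3. **Transformation** (discretionary): natural logs of named columns,
   renamed with a `log_` prefix.
4. **Power analysis**: n = ⌈N·x / ((N−1)·E² + x)⌉ with
   x = Z²·r·(100−r), r and E on the percent scale (Z = 1.96, E = 5 by
   default). This is the classical finite-population sample-size
   formula; at r = 50 its large-N limit is 385, which the tests pin
   down. The result is rounded up. For small populations the formula
   asks for nearly every row, which would leave nothing to train on,
   so `run_mcm()` caps the testing-set size at N − max(4, p + 2),
   keeping at least an estimable training set; the cap never binds at
   the population sizes (hundreds of scans) the formula is meant for.
5. **Stratified split**: testing rows drawn without replacement per
   class, proportional with largest-remainder rounding, seeded.
6. **Regression**: standard binomial logistic regression (IRLS via
   `glm.fit`), or Firth's penalized regression when any retained
   predictor separates. A fit is declared non-converged when the
   iteration cap is hit, a coefficient passes the divergence guard
   (|β| > 10⁴), or the deviance collapses to numerical zero — the
   signature of separation, under which `glm`'s own `converged` flag is
   misleadingly `TRUE`. Firth's method maximizes the Jeffreys-prior
   penalized likelihood by Newton iteration on the modified score
   U\*(β) = X′(y − p + h(½ − p)) with step-halving; the penalty is
   O(1/n), so on large non-separated samples the two fits agree (the
   suite checks 2% agreement at n = 2000), while under complete
   separation the Firth estimate remains finite.
7. **Influence diagnostics** (discretionary): standardized Pearson
   residuals (outlier threshold 3) and Cook's distances (threshold
   1.5), computed from the weighted-design hat matrix, reported as two
   separate lists.
8. **Model reduction** (discretionary): if the model-level
   likelihood-ratio test against the intercept-only model is
   significant at α = 0.05 the full model is kept — even with
   non-significant coefficients, to avoid variable-shopping. Otherwise
   the predictor with the largest Wald p-value is dropped and the model
   refitted on the same training rows, repeating. If nothing converges
   (labels carrying no signal), the full fit is kept and the failure
   recorded; erroring out would make null-calibration experiments
   impossible.
9. **Prediction**: inverse-logit of the linear predictor, clipped at
   ±30 before exponentiation so extreme fits yield probabilities
   strictly inside (0, 1); class 1 at probability ≥ 0.5. The threshold
   is symmetric because misclassification costs are not modelled.
10. **Evaluation** per set: confusion counts (per class: correctly
    recovered, pulled in from the other class), overall accuracy,
    sensitivity/specificity, accuracy-by-chance Σ(nᵢ/N)², a chi-squared
    goodness-of-fit of predicted class totals against true totals
    (df = k − 1; the construction of a scan-level chi-squared is
    genuinely ambiguous, and this reading matches the reported degrees
    of freedom, so it is used and documented), ROC and precision–recall
    curves. ROC AUC is computed by the trapezoid rule over all distinct
    thresholds, which equals the tie-aware Mann–Whitney concordance
    probability — an identity the tests assert exactly. PR AUC is
    average precision (step interpolation); under label-independent
    scores it sits at the positive prevalence, which is the correct
    null baseline for uneven classes. Confidence intervals are 95%
    percentile bootstrap, stratified by class, seeded, 2000 resamples
    by default — the number is a compromise between Monte-Carlo error
    (~1% on a CI bound) and runtime, and is configurable.

"Wald statistic" throughout means the two-sided p-value of β/SE against
the standard normal. Missing metric values are removed listwise before
modelling, with the count recorded on the result.

## What the simulator emulates — and what it does not

The simulator is a statistical stand-in, not a radiative-transfer
model. Rooms are axis-aligned boxes (default 10 × 8 m footprint, 3 m
ceiling): every ray hits a surface at its exact exit distance, plus
Gaussian range noise (sd 0.05 m, the ±50 mm ranging-error class of
compact scanners, read as a 1-sd scale), with high clipped-Gaussian
reflectance (0.8 ± 0.05) and second returns only with probability 0.01
(edge interceptions; exactly zero would make the first:second ratio
infinite on every room scan and remove it from analysis). Forests
layer three interception mechanisms: skyward pulses escape entirely
through canopy gaps with probability 0.25; otherwise the first
interception is the nearest of a trunk-cylinder hit (15 trunks in a
2–30 m annulus), an exponential free path through the understory
(0.05 interceptors/m), or a canopy surface drawn uniformly in the
8–20 m slab; interceptions beyond 40 m are dropped as no-returns.
Second returns occur with probability 0.25, a short exponential
distance beyond the first; reflectance is lower (0.45 ± 0.1). These
defaults are the package's fixed study conditions: chosen once as
plausible desk-scale magnitudes for a mid-latitude stand, and not
tuned per experiment.

Beam divergence is carried as metadata but not ray-sampled: partial
interception is summarized by the second-return probability instead of
a footprint-overlap model. Consequences worth knowing: the gap check
precedes all other interception, so the no-return ratio in the gap band
is exactly Bernoulli with the configured probability (the tests check
3-binomial-SE agreement on ~5000-pulse bands); and simulated rugosity
contrasts are driven by range noise on near surfaces versus canopy
height spread, which *reverses* the room/forest ordering one might
naively expect — flat ceilings at 3 m with 5 cm noise are "rougher"
per unit footprint than canopies, exactly the instrument-induced
effect discussed for real compact scanners. Passing tests on simulated
scenes therefore demonstrate that the metrics measure what they claim
on known geometry and that the workflow's decision logic is correct;
they do not calibrate any scene preset against a real site, and the
temperate/tropical/coastal/inland YAML presets are illustrative
contrasts only.

Default problem sizes, chosen to keep a full run in seconds-to-minutes
on one core: pulse grids of 1.5° zenith × 2.5° azimuth (8784 pulses
per scan, versus 10⁵–10⁶ for a real instrument), populations of 88
scans (32 rooms + 56 forests), ten independent populations in the
acceptance script, and per-scan jitter of ±10% on scene dimensions to
create within-class variance. All randomness flows from a single base
seed through deterministically derived per-scan seeds, so every
dataset, split, fit and bootstrap interval is exactly reproducible.

## Numerical choices

- Zenith bands are closed intervals; band membership at the optical
  plane uses the ±0.5° tolerance described above.
- Delaunay triangulation uses a fast sweep-hull implementation, with a
  fallback to a slower, robust implementation on highly regular
  (cocircular) configurations that defeat the former — noise-free
  synthetic ceilings being the one practical case. Coincident
  projections are collapsed before triangulating; collinear inputs are
  reported as not-computable rather than triangulated.
- The shoelace area is taken as an absolute value, so vertex
  orientation never matters; azimuth ties are broken by distance to
  keep the ordering deterministic.
- Logistic fits clip linear predictors at ±30 (p within ~10⁻¹³ of the
  bounds) everywhere probabilities are formed; the Firth Newton stops
  on a 10⁻⁸ score norm with at most 100 iterations.
- Stratified allocation uses largest-remainder rounding so per-class
  test counts never deviate from proportionality by more than one.

## Known limitations

- No real-instrument ingestion: the CSV dialect is the only input
  format; binary vendor formats and multi-scan registration are out of
  scope.
- Scene presets are not calibrated; coefficient magnitudes from
  simulated data are on the simulator's intensity scale (intensities
  normalized to [0, 1]) and are not comparable to values fitted on any
  particular instrument's units.
- The binomial response is the only implemented model family; the
  workflow's structure would accept multinomial or continuous
  responses, but none is provided.
- Scans are treated as independent; spatially overlapping scans
  violate this silently, and the package offers no correction.
- The chi-squared stage tests class totals, not per-scan agreement;
  significant values flag frequency mismatch, not which scans erred.
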