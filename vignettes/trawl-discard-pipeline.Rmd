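---
title: "Assessing fisher self-reported trawl data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing fisher self-reported trawl data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trawlwatch)
```

## The problem

Small-scale bottom-trawl fleets are hard to monitor: many small vessels, no
room for observers, and — where the fishery is informal or illegal — no
institutional data stream at all. Smartphone self-reporting offers position
tracks at a few-minute cadence plus per-haul catch weights, but the data
arrive noisy and incomplete: tracking left on in port, missing catch forms,
half-recorded tracks. `trawlwatch` implements the full chain needed to turn
such self-reports into effort and discard maps and to ask the critical
question: *do fisher-derived maps and discard rates agree with
observer-derived ones?*

Because real fleets of this kind rarely publish their raw data, the package
ships a first-class synthetic fleet generator with complete ground truth, so
every stage — cleaning, activity classification, discard accounting,
rasterization, map comparison — can be validated end to end.

## The synthetic fleet

`fleet_config()` fixes the study conditions; `simulate_fleet()` draws trips.
The defaults describe a night-operating shrimp-trawl fleet off a
north–south coastline at about 4°S:

* **Fleet and schedule.** 9 vessels, 8–53 trips each over October–March,
  3–6 hauls per trip. Trips depart port between 18:00 and 22:00 local
  (UTC−5) and return before the following noon, so one night trip maps to
  one noon-to-noon "fishing day".
* **Kinematics.** Towing at 2–3 knots for 2–3 h per haul; steaming at
  4–6.4 knots (the fleet-wide ceiling is 6.5 knots, and towing speeds sit
  strictly below it so genuine fishing fixes always survive the speed
  filter). Positions are emitted every 180 s with isotropic Gaussian GPS
  noise (default sd 10 m, typical of consumer phone receivers). Tow paths
  reverse heading every 20–40 minutes — vessels work a ground back and
  forth rather than steaming away down-path — with wrapped-normal turning
  noise of sd 10° per step (30° on transit legs). These two turning scales
  are invented: they make the classification problem realistic rather than
  trivial, without encoding the classifier's own features.
* **Fishing grounds** are placed within 15 km of the port and at least
  1.5 km off the coast. Keeping grounds within a night's steaming of the
  home anchorage mirrors fleets whose effort concentrates off the home
  town and keeps trips inside one fishing day.
* **Discards.** Each trip's true discard proportion is
  `mid(discard_range) + 0.008/km southward − 0.006/km offshore + N(0, 0.05)`,
  evaluated at the trip's mean haul location and clamped to `[0.19, 0.95]`.
  The gradient signs encode the qualitative field pattern (more discarding
  in the south and inshore); the magnitudes are chosen so the proportion
  spans most of its admissible range across a ~40 km study area. The
  trip-level noise term is deliberate: real per-trip discard proportions
  scatter widely, and without residual variance a "recovered within 2
  standard errors" check would be vacuous.
* **Catch weights.** Per-haul totals are log-normal (median 50 kg, log-sd
  0.4); the commercial fraction `1 − Dp` is split across the six reportable
  commercial species with Dirichlet weights dominated by the target shrimp.
  Trip weights are internally consistent, so the discard module's `Dp`
  reproduces the generator's `true_Dp` exactly — a deliberate identity used
  as a cross-module test.
* **Reporting errors.** Independently per trip: catch records lost with
  probability 0.25 (the rate at which tracked trips lack catch data in
  fleets of this kind), all fixes lost with 0.05, track truncated below 50
  fixes with 0.08 (the two routes by which catch-only trips arise, in
  roughly their observed 14:23 ratio), plus exact-duplicate fixes and fixes
  displaced onto land near port. An error ledger records every defect and
  reconciles record counts exactly.
* **Seeding.** One master seed; every trip draws from a child seed derived
  from (seed, vessel, date), so any single trip is reproducible in
  isolation and fleet-level results are order-independent.

What the generator does *not* emulate: currents and gear effects on speed,
within-haul catch heterogeneity, under-reporting incentives (errors here are
omissions, never biased values), real shoreline geometry, or target-species
switching. Passing tests therefore demonstrate that the pipeline's logic is
correct under honest-but-sloppy reporting; they do not certify robustness to
deliberate misreporting or to coastlines more complex than the configured
polyline.

## Track cleaning

`clean_pipeline()` composes seven steps; each removal is recorded with a
reason so that `input = retained + removed` holds per filter and per trip
(an invariant the tests assert):

1. **Assembly** by vessel × fishing day, with the day boundary at local
   noon. A calendar-date boundary would bisect nearly every night trip;
   noon-to-noon keeps one trip whole. Exact duplicate rows collapse to one.
2. **Study area and land**: fixes outside the configured bbox, on land, or
   within 10 m seaward of the coastline are removed. The coastline is a
   configurable polyline with a declared land side — no shapefiles needed.
3. **Speed**: a sequential forward pass removes fixes whose arrival speed
   from the last *retained* fix exceeds 6.5 knots. The sequential form
   prevents one bad fix from deleting its valid neighbour; distances are
   haversine on WGS84.
4. **Gaps**: a fix isolated across a >5 km jump (both neighbours far, or a
   lone endpoint) is removed, iterating until stable.
5. **Endpoint buffer**: fixes within 500 m of the first or last retained
   fix are *flagged*, not deleted. The buffer exists to keep slow anchorage
   milling out of activity classification; deleting would also bias effort
   summaries that legitimately include transit, so exclusion is deferred to
   the classifier.
6. **Validation**: trips shorter than 3 h or with fewer than 50 retained
   fixes are rejected (point-level filters run first, so validation judges
   what actually survives).
7. **Regularization** to exact 180 s spacing by linear interpolation in
   lon/lat between bracketing fixes, never extrapolating. At 4°S over
   ≤3-minute steps the planar error of interpolating in geographic
   coordinates is far below GPS noise. Interpolated positions are convex
   combinations of their brackets, and segment speeds can only decrease, so
   the pipeline is idempotent: re-cleaning cleaned output changes nothing.

All storage is UTC; the local clock (UTC−5) is used only for fishing-day
assignment and the time-of-day feature.

## Inferring trawling activity

Where haul start/end times exist (observers, or simulator truth), fixes are
labelled by closed-interval overlay. Elsewhere a random forest predicts
per-fix state from three features: step distance to the previous regular
fix, turning angle in (−180°, 180°], and local time of day encoded as
(sin, cos) of the fractional hour — a raw hour would fracture midnight,
exactly when this fleet fishes. The first two fixes of a trip have no
turning angle; they are excluded from training (<1% of fixes) and inherit
the trip's first computable prediction. Endpoint-buffer fixes are forced to
`not_trawling`.

Hyperparameters are conventional forest defaults — 500 trees, `sqrt(p)`
candidate features per split, unlimited depth — exposed in
`train_classifier()`. Evaluation uses vessel-level splits
(`split_by_vessel()`), never fix-level ones, because fixes within a vessel
are strongly autocorrelated and a fix-level split would leak. Accuracy is
the plain fraction of correctly classified fixes over both classes. On the
default synthetic fleet with a 7-of-14-vessel split the held-out accuracy
is ~0.999: towing and steaming speeds barely overlap at 10 m GPS noise, so
the synthetic task is easier than a real fleet's (where hauling, drifting
and slow steaming blur the envelope); the tests therefore treat 90% as a
floor, not a point target. A run-length smoother (`smooth_states()`,
dropping trawling runs shorter than 3 fixes) is available but off by
default: at a 3-minute cadence real hauls last 40+ fixes and the per-fix
forest already respects that scale.

## Discard accounting

The discard proportion of a trip is `Dp = (Tc − Cc)/Tc`, with `Tc` the sum
of per-haul total weights and `Cc` the per-trip sum of commercial-species
weights. `Dp` is computed per trip, not per haul, because commercial
weights are reported per trip. Domain violations (`Tc = 0`, `Cc > Tc`)
raise errors naming the trip — silent clamping would hide data-entry
problems. Trips lacking a species table keep `Tc` with `Dp` flagged
missing.

`reconcile()` partitions reported trips into track+catch, track-only and
catch-only — disjoint and exhaustive by construction. `calibrate_weights()`
regresses the fisher's estimated haul weight on the observer's measured
weight (observer on the x-axis as ground truth);
`simulate_calibration_pairs()` generates synthetic pairs under a given
intercept/slope/R² with the noise variance solved from the uniform
predictor variance, so recovery of the generating slope is a genuine test
of the estimator. Calibration is optional and off by default in `Dp`
computations, since self-reported weights are the quantity actually
available at scale. `monthly_summary()` emits the tidy month × reporter
table (n, mean, median, IQR) that downstream month-contrast models consume;
fitting those models is deliberately out of scope.

## Grids and map comparison

`grid_spec()` lays a 500 m grid over the study bbox in a local
equirectangular projection centred on the bbox — a deliberate lightweight
choice: over a 0.4° box at 4°S its distortion is centimetres, and it keeps
the package free of GDAL-class dependencies. The origin is the projected
bbox corner snapped down to the cell size, so a given bbox always yields
the same reportable alignment; cells are half-open `[x, x+500) × [y, y+500)`.

`rasterize_effort()` counts trawling fixes per cell × 3 minutes; unfished
cells are *missing*, never zero — the distinction matters downstream.
`rasterize_discards()` assigns each trip's `Dp` to its trawling fixes and
takes the per-cell mean, which weights trips by their fix counts.
`normalize_grid()` min–max rescales to [0, 1]; a constant grid maps to 0 so
the comparison below stays defined.

The similarity-in-means index compares two maps through local means: each
cell is replaced by the mean of its 3×3 neighbourhood (truncated to in-grid
cells at edges), cells are compared as `1 − |mA − mB|`, and the overall
index is the unweighted mean over valid cells. With inputs in [0, 1] the
index runs from 0 (opposite local usage) to 1 (identical local usage), is
symmetric, and tolerates the spatial autocorrelation inherent in
track-derived maps. Published descriptions of such indices leave the
missing-data contract open, so this package fixes one and exposes the
alternatives: by default a cell is valid when *either* map has data there
(`valid_rule = "either"`), and a missing cell inside a window contributes 0
usage over the full in-grid denominator (`fill = "zero"`) — absent effort
is evidence of non-use, not of no observation. Both switches accept the
stricter alternatives (`"both"`, `"drop"`). An independent brute-force
implementation in the test suite pins the fast box-filter version to
machine precision.

`sim_by_period()` produces monthly indices plus a pooled-period index;
pooling sums effort grids elementwise (minutes add), while pooled discard
grids should be rebuilt from the pooled fixes, since means do not add.

## Numerical and statistical notes

* **Knots**: 1 kn = 0.5144 m/s throughout; distances use the haversine
  radius 6378137 m (111,319.5 m per degree), matching the projection.
* **Gradient recovery checks** regress on *both* southward and offshore
  distance — the two terms the generator uses. At a few hundred trips the
  chance correlation between the two distances is large enough that a
  single-covariate fit can be pushed outside a 2-SE band by omitted-variable
  bias alone.
* **Cell-level inference**: every cell a trip touches shares that trip's
  `Dp`, so residuals of a cell-level regression cluster by trip and the
  naive OLS standard error is several-fold too small; gridded covariates
  are also mildly attenuated (~10%) relative to trip-level ones. The test
  suite therefore bootstraps whole trips (resample trips, re-rasterize,
  refit) to obtain the standard error for the rasterized gradient check.
* **Calibration recovery**: at 162 hauls and R² ≈ 0.9 the per-replicate
  slope SE is ≈ 0.026, so individual replicates land within ±0.05 of the
  generating slope about 95% of the time, while the 100-replicate mean is
  comfortably within ±0.02; the tests assert exactly that.
* **Problem sizes**: validation runs use a 14-vessel, ~320-trip fleet
  (~90,000 fixes) for the classifier check and 9-vessel, 200–260-trip
  fleets for gradient, reconciliation and similarity checks — large enough
  for the binomial and regression bands above to be meaningful, small
  enough to simulate in seconds.

## Known limitations

The simulator's behavioural repertoire is minimal (no drifting, hauling
pauses, or weather aborts), its coastline is schematic, and reporting
errors are unbiased omissions — so agreement metrics computed on synthetic
fisher/observer pairs bound what honest reporting looks like, not what
strategic under-reporting does. The activity classifier is per-fix; fleets
with gear whose towing speed overlaps steaming speed would need the state
sequence modelled explicitly. The equirectangular grid is appropriate for
study areas up to a degree or so; continental-scale work should substitute
a proper projected CRS.
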