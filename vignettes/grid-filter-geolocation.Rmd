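---
title: "Grid-filter geolocation and space-use analysis: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-filter geolocation and space-use analysis: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Archival satellite tags on large marine animals such as basking sharks
(*Cetorhinus maximus*) record light, temperature and depth, from which a
daily position can be inferred — but raw light-based fixes are very noisy,
especially in latitude (standard deviations of about 1° in longitude and
3.5° in latitude, i.e. hundreds of kilometres). Argos Doppler fixes are far
more precise but exist only when the animal surfaces, which is rare in
winter. This package reconstructs daily position *probability surfaces*
from the archival stream with a hidden Markov model (HMM) implemented as a
grid filter, and then carries those surfaces through the downstream
analyses a movement ecologist needs: track metrics, utilisation
distributions and percentage volume contours, hexagonal density surfaces,
zone occupancy, migration-strategy classification and depth-use profiles.

## The state-space model

The hidden state on day $t$ is the grid cell occupied by the animal, on a
regular lon/lat grid whose land cells (bathymetry $= 0$) are excluded.

**Prediction.** Between days the state evolves by the advection–diffusion
equation for the two-dimensional probability $p(x, y, t)$ of presence,

$$\partial_t p = D \nabla^2 p - \mathbf{u} \cdot \nabla p,$$

with diffusion coefficient $D = 1{,}000\ \mathrm{km^2\,d^{-1}}$ by default
and zero advection velocity $\mathbf{u}$ (the velocity is kept in
`filter_config()` for generality, but a plain diffusion kernel is the
default behaviour). $\sqrt{2Dt}$ is then the per-axis positional spread
after $t$ days of unobserved movement, about 45 km per day.

**Update.** Each day's observations enter as independent likelihood
fields evaluated at the cell centroids:

* light fix: Gaussian in longitude ($\sigma_{\mathrm{lon}} = 1^\circ$) and
  latitude ($\sigma_{\mathrm{lat}} = 3.5^\circ$);
* tag SST vs a gridded SST field: Gaussian with
  $\sigma_{\mathrm{SST}} = 0.5\ ^\circ\mathrm{C}$;
* daily maximum depth vs bathymetry: a hard mask — a cell is admissible
  only if its seafloor is at least as deep as the day's maximum dive.

The posterior is prior × likelihoods, renormalised. A missing observation
contributes a flat field; a day with no observations is predict-only.

**Anchors and smoothing.** Day 0 is a point mass at the known deployment
location. When a pop-off position is known, the final day is anchored at
the pop-off cell and a backward (beta) recursion propagates the constraint
through the whole track, giving forward–backward smoothed marginals;
without a pop-off the output is the filtered marginals. Both code paths
exist because tag data sometimes lack a usable pop-off position.

The best single location per day is the geographic mean of the cell
centroids weighted by posterior probability — a weighted arithmetic mean in
degrees, which is adequate because the domains span well under a
hemisphere and posteriors are unimodal after the update.

## Numerical choices

* The prediction step is a flux-form explicit finite-difference scheme
  with internal sub-stepping so that $D\,\delta t/\Delta x^2 \le 0.25$ per
  axis per sub-step. Flux form makes mass conservation exact (to machine
  precision) and guarantees non-negativity under that bound.
* Coastlines and domain edges are no-flux (reflecting): probability never
  leaks onto land, and total mass is conserved, so every posterior sums to
  1 within $10^{-9}$.
* Longitudinal cell width scales with $\cos(\mathrm{lat})$ of the cell
  row; the grid itself stays in degrees, which matches observation SDs
  being specified in degrees.
* The explicit scheme has finite propagation speed (one cell per
  sub-step). At the default $D$ and 1° cells the daily reachable set grows
  faster than a shark can swim, so this is not a practical restriction,
  but idealised test scenarios must respect it.
* The flux-form diffusion operator is self-adjoint, so the same operator
  application serves the backward smoothing recursion. With a non-zero
  advection velocity the kernel is no longer symmetric and the smoothing
  pass would need the transpose operator; since the analysis runs with
  pure diffusion, smoothing is only supported (and only tested) for the
  zero-advection default.
* If the day's likelihood product is identically zero, constraints are
  dropped in a fixed order — depth mask first, then SST — each with a
  warning; only if the light fix itself annihilates the prior does the
  filter stop with an error naming the date. The order reflects which
  observation is most often degenerate in practice (a deep dive recorded
  just off the grid's shelf edge).
* Contradictory inputs are surfaced, not silently repaired: an
  observation deeper than any grid cell yields an all-zero mask flagged
  `contradictory`.

Validation: on grids of up to ~100 cells the filter and smoother marginals
are compared against an independent dense-matrix forward(–backward)
algorithm and agree to better than $10^{-10}$; a point mass diffused for
one day on a fine grid reproduces the analytic per-axis variance $2Dt$
within 2%.

## Track metrics conventions

* Great-circle (haversine) distances on a 6,371-km sphere.
* Argos speed filter: class-Z fixes always removed; a forward pass retains
  a fix only if the implied speed from the last retained fix is below
  `vmax` (default 9 km/h, generous for sustained basking-shark swimming;
  exposed as an argument).
* Daily reduction keeps the best location class per UTC day
  (3 > 2 > 1 > 0 > A > B), ties broken by proximity to 12:00 UTC.
* Cohort summaries use linearly interpolated quartiles (R's default
  type 7).

## Space use

* A utilisation distribution is the normalised mean of daily posteriors
  over a period; "post-summer" is fixed to days from 1 October onwards.
* A percentage volume contour at level $q$ takes cells in descending
  probability order until cumulative mass reaches $q/100$. Ties at the cut
  are broken by stable cell order, so the mask has minimal cardinality
  (verified against exhaustive subset enumeration on small instances).
* Hexagonal sampling grids are regular flat-topped hexagons laid out in a
  local azimuthal-equidistant projection about the extent centre, so the
  50-km default apothem is metric; the cell area is
  $2\sqrt{3} \cdot 50^2 = 8{,}660\ \mathrm{km^2}$. The 50-km default
  follows the ~100-km positional error of light-based geolocation: cells
  much smaller than the error would only map noise.
* Point locations are assigned to hexagons by exact containment
  (axial-coordinate rounding); posterior rasters are apportioned by
  raster-cell centroid. Centroid apportionment rather than areal weighting
  is deliberate: its error is far below the geolocation error that sets
  the cell size. Per animal, cell weights are proportions of tracking
  days, so each animal contributes equally to the across-animal mean
  regardless of tag duration.
* Zone occupancy assigns each animal-day to the first zone polygon (input
  order) containing it, with a "High Seas" remainder, and reports raw
  percentages of animal-days.

## Migration strategies and depth use

Animals are clustered on the southernmost latitude of their best daily
locations with k-means (`stats::kmeans`, Lloyd's algorithm, 25 random
restarts under a fixed seed, best within-cluster sum of squares kept;
standardisation is moot for a 1-D input). `k = 3` by default, reflecting
the three recognised strategy amplitudes; clusters are relabelled
`a`, `b`, `c` by decreasing mean latitude (ties by cluster size), so `a`
is always the shortest-range strategy.

Daily maximum depths are profiled over eight bins — 0–25, 26–50, 51–100,
101–200, 201–500, 501–750, 751–1,000 and >1,000 m — interpreted as
right-closed intervals ((25, 50] etc.), consistent with the integer-metre
bin labels: a 25.5-m day falls in the second bin. The epipelagic fraction
(days ≤ 200 m) is identically the sum of the first four bins.

## What the synthetic data emulate — and what they do not

The generator exists so the whole chain can be exercised and its error
quantified against a known truth, without proprietary tag downloads.

* **Environment**: SST with a monotone north–south gradient
  (−0.35 °C per degree latitude), a ±3 °C seasonal cycle peaking in
  mid-August, and a smooth spatial anomaly (0.6 °C scale); bathymetry with
  a sinuous eastern coastline, a < 200 m shelf, a slope and a > 2,000 m
  abyssal plain. The SST gradient is what lets an SST observation carry
  ~1.4° of latitude information (0.5 °C noise / 0.35 °C per degree), the
  mechanism by which the filter beats the 3.5° raw light fixes.
* **Movement**: a biased correlated random walk (velocity persistence
  0.6, innovation SD 8 km/day per axis, drift capped at 30 km/day, daily
  displacement capped at 150 km). From 1 October the drift targets a
  wintering latitude 3°, 10° or 20° south of the deployment for
  strategies a, b, c; from 1 March it targets the deployment again,
  producing a return migration. These amplitudes put the three strategies'
  southernmost latitudes far enough apart that classification is testable,
  while staying inside observed basking-shark ranges.
* **Observations**: light fixes = truth + N(0, 1°) lon, N(0, 3.5°) lat,
  missing completely at random with probability 0.1 per day (reported
  per-day fix availability is not well constrained, so the rate is a
  parameter); SST = field + N(0, 0.5 °C); daily maximum depth drawn from a
  lognormal (median 110 m, log-SD 0.8) capped by local bathymetry and a
  1,250-m physiological ceiling, putting most days in the 50–200 m band;
  Argos fixes with seasonal surfacing probability (0.7 summer, 0.15
  winter) and class-dependent errors of 0.25, 0.5, 1, 2, 5 and 10 km for
  classes 3, 2, 1, 0, A, B — conventional Argos error magnitudes.

Not emulated: diel vertical migration, any coupling between depth use and
strategy (so per-strategy depth contrasts in synthetic output are flat by
construction), foraging behaviour, currents/advection, real coastline
geometry and real maritime-zone polygons. Passing tests therefore
demonstrate that the estimators are correct and that the filter recovers
tracks under the stated noise model — not that any particular biological
result would be obtained from real tags.

## Problem sizes used in validation

The shipped validation runs use a 30° × 34° domain at 1° filter
resolution (about 1,000 sea cells), cohorts of 12–20 animals tracked
for 300–330 days, and the default noise levels above. On this setup the
smoothed best daily locations have ~60–65 km RMSE against truth versus
~395 km for raw light fixes (an improvement of over 80%), strategy
recovery is exact, and all bookkeeping invariants hold. Oracle comparisons
use 20–100-cell grids where dense-matrix computations are feasible.

## Known limitations

* The weighted-mean daily location is computed in degrees, not on the
  sphere; negligible for sub-basin domains but wrong near the poles or the
  antimeridian.
* The depth constraint is a hard mask; a soft (error-aware) bathymetry
  likelihood would be more forgiving of tide and datum mismatches.
* $D$ is fixed, not estimated; the filter is a reconstruction tool, not a
  movement-parameter estimator.
* Zone occupancy with real EEZ shapefiles (multi-ring, holes) would need a
  full GIS geometry engine; the built-in reader handles single outer-ring
  polygons.
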