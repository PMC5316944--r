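# basktrack

Hidden-Markov-model geolocation and space-use analysis for satellite-tagged
marine animals, built around the tracking workflow used for basking sharks
(*Cetorhinus maximus*) in the north-east Atlantic.

Archival pop-off tags record light, sea-surface temperature (SST) and depth.
Raw light-based position fixes are extremely noisy — standard deviations of
about 1° longitude and 3.5° latitude — so `basktrack` reconstructs daily
position *probability surfaces* with an HMM implemented as a grid filter:

* **prediction**: the advection–diffusion equation for the probability of
  presence, `∂p/∂t = D ∇²p` with `D = 1,000 km² day⁻¹`, solved by a
  mass-conserving explicit finite-difference scheme with reflecting
  coastlines;
* **update**: Bayes multiplication by per-day likelihoods — Gaussian light
  fix (σ 1°/3.5°), Gaussian SST mismatch (σ 0.5 °C) and a bathymetric mask
  from the day's maximum dive depth;
* **anchoring**: a point mass at the known deployment position, and
  forward–backward smoothing to the known pop-off position when available.

The best daily location is the probability-weighted geographic mean of the
grid centroids. Downstream, the package computes track metrics (speed-filtered
Argos daily locations, along-track distance, displacement, monthly minimum
latitudes), utilisation distributions with percentage volume contours,
50-km-apothem hexagonal density surfaces (cell area 2√3·50² = 8,660 km²),
zone-occupancy percentages, k-means classification of migration strategies
from southernmost latitude, and depth-use profiles over the standard eight
daily-maximum-depth bins. A synthetic-data module (environment fields, biased
correlated random-walk migrations of three amplitudes, noisy tag
observations) makes the whole chain testable against a known truth.

## Worked example

The `analysis/` scripts run the full study on a simulated 12-animal cohort
(run them in order; stage 1 writes the observation CSVs that the later
stages consume):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_geolocate.R
Rscript analysis/03_track_metrics.R
Rscript analysis/04_space_use.R
Rscript analysis/05_strategies.R
```

The stages write their tables under `results/` and print (seed 2017):

```
Simulated 12 animals over 330 days each.
Strategy mix: a 6, b 5, c 1
Mean RMSE: raw light fixes 395 km, smoothed HMM locations 61 km (85% lower).
Along-track distance: median 6757 km (IQR 6147-6921).
Max displacement: median 796 km (range 354-2307).
Hex grid: 1784 cells of 8660 km^2 (apothem 50 km).
Strategy recovery: 12 of 12 animals labelled as generated.
Mean southernmost latitude by strategy: a = 52.2, b = 45.2, c = 35.5
Epipelagic (0-200 m) fraction: cohort mean 77%
```

Read it as: the grid filter cuts the positional error of the raw light
fixes by about a factor of six (395 → 61 km), which is what makes the
downstream biology — migration amplitudes several hundred to two thousand
km, three cleanly separated strategies — recoverable from noisy tags. The
same functions are available programmatically; `run_pipeline(pipeline_config())`
drives all five stages from one configuration object (or a YAML file via
`read_pipeline_config()`).

## Repository layout

* `R/` — the package: simulation, grid filter, track metrics, space use,
  strategy analysis, pipeline orchestration.
* `analysis/` — numbered narrative drivers over the package.
* `tests/testthat/` — unit, property and end-to-end validation suites,
  including dense-HMM oracle comparisons.
* `vignettes/grid-filter-geolocation.Rmd` — the models, parameter choices
  and limitations, in detail.
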