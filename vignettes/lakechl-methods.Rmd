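---
title: "lakechl: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lakechl: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lakechl)
```

## What the package computes

`lakechl` turns per-scene satellite retrievals of inherent optical
properties (IOPs) of lake water into three products: a quality-controlled
table of satellite vs in-situ chlorophyll match-ups, a regionally
calibrated chlorophyll product, and a per-pixel "patchiness" composite
that maps how often each location of a lake sits near the lake-wide
median (or quartiles) of chlorophyll — the quantitative basis for choosing
representative monitoring sites.

The upstream physics (atmospheric correction, neural-network IOP
retrieval, cloud classification) is out of scope by design: the package
consumes its *outputs* — absorption rasters and pixel flags — and the
synthetic generator fabricates exactly that contract.

## The chlorophyll model

All chlorophyll values derive from the three-parameter model

$$\mathit{Chl} = A\,\bigl(a_{pig} + B\,(a_{det} + a_{cdom})\bigr)^{C},$$

with the canonical regional coefficients $(A, B, C) = (21, 0.77, 1.04)$;
absorptions in m$^{-1}$, chlorophyll in mg m$^{-3}$. The model is strictly
increasing in each absorption, maps zero absorption to zero chlorophyll,
and scales as $s^{C}$ when the inner term is scaled by $s$.

**Refitting.** `fit_regional_coefficients()` minimizes squared residuals
of $\log \mathit{Chl}$ — chlorophyll spans orders of magnitude across a
trophic gradient, and log residuals weight oligotrophic and eutrophic
lakes comparably; the loss function of the original regional fit is not
public, so this is the package's own documented choice. Parameters are
kept positive by optimizing $(\log A, \log B, \log C)$: a Nelder–Mead
stage followed by a guarded L-BFGS-B polish (the polish occasionally
aborts its line search on noisy data, in which case the simplex solution
is already converged). Diagnostics ($r^2$ as squared Pearson correlation,
RMSE) are reported on the *linear* mg m$^{-3}$ scale, the convention used
when such calibrations are published. Because it is ambiguous which
parameters were free in the original calibration, `fix_AC = TRUE` freezes
$A$ and $C$ and refits only the non-pigment weight $B$; the default frees
all three.

## Quality control constants

| parameter | default | meaning |
|---|---|---|
| `buffer_distance` | 120 m | inward shoreline erosion (mixed pixels, adjacency) |
| `secchi_quantile` | 0.95 | Secchi-depth quantile defining the shallow-water exclusion |
| `matchup_window_hours` | 24 | max \|in-situ − overpass\| time difference |
| `macropixel_size` | 3 | 3×3 block (180 m × 180 m at 60 m pixels) |
| `min_valid` | 6 | minimum valid macropixel cells |
| `homogeneity_threshold` | 0.20 | population std / median bound (strict `<`) |
| `band_tolerance` | 0.05 | ±5% relative quantile bands |
| `coverage_threshold` | 0.5 | minimum unflagged fraction per scene (inclusive `≥`) |

Decisions the printed constants do not settle, resolved here and recorded
in output metadata:

* **Quantile rule** — linear interpolation between order statistics
  (R type 7) everywhere a quantile is taken; it reproduces the worked
  values used in the package's tests exactly (e.g. depths 1..100 m at
  q = 0.95 give 95.05 m).
* **Standard deviation** — population form ($\div n$) over the valid
  macropixel values; with ≥ 6 values the difference from the sample form
  never flips a realistic decision, but the choice is fixed and tested.
* **Boundary inclusivity** — the 24 h window and the ±5% band bounds are
  inclusive; the homogeneity bound and the coverage rule are as printed
  ("less than 20%", "at least half"): strict `<` and inclusive `≥`
  respectively.
* **Rasterization** — pixel membership is by pixel-centre point-in-polygon
  test; membership in a buffered outline is evaluated by the exact erosion
  criterion (inside the source outline *and* at least the buffer distance
  from its boundary), which is immune to offset-curve artefacts.
* **"Shallower than"** — a pixel is excluded when its bottom depth is
  below the Secchi quantile, with all Secchi samples of the lake pooled.
* **Cloud buffer metric** — square (Chebyshev) structuring element of
  radius 2 pixels; the upstream tool does not define the metric.
* **Multiple pairings** — a sample within 24 h of several scenes yields
  several candidate records; no deduplication is applied.

## The synthetic world

The generator states a world and sticks to it; its defaults are the
conditions the pipeline is designed for, not tuning knobs.

* **Grid** — 60 m cells (the working resolution after resampling
  multispectral bands to the coarsest band), default 50×50 with a 900 m
  radius lake (~700 lake pixels, the size class of the smaller study
  lakes). Bathymetry is a smooth bowl, $z = z_{max}(1 - t^2)$ with $t$
  the relative radial position and default $z_{max} = 25$ m.
* **Truth** — per-pixel chlorophyll is
  `base_chl × pattern × temporal_factor × noise`: a persistent
  multiplicative spatial `pattern` normalized to lake-mean 1 (the planted
  patchiness), a lake-wide per-scene `temporal_factor` (default seeded
  lognormal, sdlog 0.3 — a realistic seasonal spread; the source material
  states no value), and i.i.d. mean-1 lognormal pixel noise with
  `noise_cv = 0.1`. A multiplicative lognormal error model is the natural
  choice for a positive, right-skewed concentration; no error model is
  stated upstream.
* **IOPs** — each scene's absorptions are obtained by inverting the
  chlorophyll model so the forward model reproduces the truth to round-off
  (`iops_from_chl()`). The pigment share of the inner term is drawn per
  pixel from U(0.5, 0.85) rather than fixed: with a *fixed* share,
  $a_{pig}$ and $a_{det}+a_{cdom}$ are exactly collinear and $(A, B)$ lie
  on a ridge of equivalent fits — no calibration experiment could recover
  them. A seeded variable share keeps the identity exact, the generator
  deterministic, and all three coefficients identifiable.
* **Clouds and flags** — one random disc per scene with area
  `cloud_fraction` × lake area (contiguous, like real cloud), its 2-pixel
  dilation as the cloud buffer, and independent Bernoulli noise on the
  remaining negative flags. Scenes arrive at a fixed 5-day cadence
  (a Sentinel-2-like revisit).
* **Surveys** — one sample per station per scene at the station pixel's
  true value times mean-1 lognormal noise (`measurement_cv = 0.1`, a free
  simulation parameter: no in-situ error model is published), with
  sampling instants offset from overpasses by stated hours. Stations sit
  at the deepest pixels, mirroring monitoring practice.

**What a green test establishes — and what it does not.** The generator
emulates the *contract* of the upstream processors, not their physics: no
radiative transfer, no spectral bands, no retrieval error correlated with
atmospheric state, no adjacency gradients, and clouds are single discs,
not fronts. Green tests establish that the masking, QC, calibration and
composite logic are correct and self-consistent on data obeying the
stated contract; they do not validate the upstream retrievals, and the
published accuracy of the original regional product (r² = 0.79,
RMSE = 5.4 mg m⁻³ against its own archive) is not reproducible — nor
claimed — without that archive.

## The patchiness statistic and the terraced test pattern

For each participating scene (coverage ≥ 0.5, ≥ 4 valid values), pixels
within ±5% of the scene's Q50/Q25/Q75 are flagged, and per-pixel
frequencies are accumulated. The default denominator is the number of
participating scenes in which *that pixel* was valid, so pixels under
recurrent cloud are not penalized; `denominator = "all_scenes"` is
available, since the original accounting ("across all scenes") is
ambiguous. Band assignments are scale-invariant (quantiles and bounds
scale together), so the composite is insensitive to lake-wide temporal
factors.

The pattern-recovery test asserts that the pixel whose pattern value is
closest to the lake-median pattern attains the maximum near-median
frequency. A power analysis done *before* writing the test shows this is
statistically meaningful only for particular planted patterns: with a
smooth gradient, pixels whose pattern values differ by < 2% have
near-median band probabilities within 0.01 of each other — far below the
binomial noise of a 100-scene count — so the single-pixel argmax is a
coin flip among near-ties; with a gapped two-level pattern the scene
median itself jumps across the gap whenever a contiguous cloud removes
more of one level than the other. The `"terraced"` pattern resolves the
tension: a central plateau at exactly the median value, wide enough
(~28% of lake pixels) that the scene median stays pinned to the plateau
under any 20% contiguous removal, flanked by terraces ≥ 15% away whose
in-band probability (~0.11 at noise_cv = 0.1) cannot beat the plateau's
(~0.38) even as a maximum over hundreds of pixels. All plateau pixels are
equidistant (distance 0) from the median, so "the closest pixel" is read
as the tied closest set and the test asserts the argmax lies in it.

Test sizing follows the same logic: the pattern-averaging check uses 400
cloud-free scenes so that the stated per-pixel tolerance
$3\,c_v/\sqrt{200}$ sits at ~4σ of the 400-scene mean, making an
all-pixel assertion reliable; and the calibration-recovery fixture draws
the pigment share from U(0.2, 0.95) — a designed experiment spanning
pigment- to CDOM-dominated waters — because the narrower generator
default leaves the $B$ coefficient too weakly identified for a 10%
bound at n = 200 with 10% noise.

## Numerical choices and degenerate inputs

* Quantiles: type-7 linear interpolation, logged in output metadata.
* The calibration requires ≥ 5 match-ups and positive in-situ values;
  non-convergence is an explicit error, never a silent fallback.
* `evaluate_fit()` reports `r_squared = NA` with a warning when either
  vector has zero variance.
* A macropixel median ≤ 0 rejects the record with reason
  `nonpositive_median` (real retrievals can produce near-zero values).
* An empty buffered polygon (over-buffered small lake) and an empty
  valid-water mask (exclusion depth above the deepest point) are reported
  with warnings, not dropped silently; a lake smaller than 5×5 cells is
  rejected outright because a 120 m buffer would erase it.
* Scene series must be strictly time-increasing and on one grid; writers
  serialize doubles as `%.17g`, so read–write round trips are bit-exact.
* All randomness flows through per-stage seeds derived from one
  experiment seed (kept below $2^{31}$), so reruns are byte-identical.

## Known limitations

* Geometry is planar (projected metres); no geodesic buffering. The
  lat/lon CSV boundary uses a local equirectangular tangent plane —
  exact to invert, adequate at lake scale, not a general projection.
* The text-based scene container and ASCII-grid rasters stand in for the
  netCDF/GeoTIFF archive formats of a production deployment; the schemas
  (CF-style flag metadata, band order, nodata) mirror them so swapping
  the carrier is an io-module change only.
* No uncertainty propagation from flags or retrieval covariances into
  the match-ups or the composite.
* The self-intersection screen on polygons is a cheap heuristic suited
  to the smooth outlines the package produces or reads, not a full
  planar-topology validator.
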