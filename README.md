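# lakechl

Satellite lake chlorophyll: match-up quality control, regional calibration
and recurring-patchiness mapping.

## The problem

Lake monitoring programmes usually sample chlorophyll-a (*Chl*, mg m⁻³) at
one or two fixed stations per lake and treat those values as lake-wide
averages — an assumption of representativeness that is rarely tested.
Satellite imagery observes the whole lake surface at once and can test it:
given per-scene inherent optical property (IOP) retrievals from an
atmospheric-correction processor (pigment absorption `a_pig`, detritus
absorption `a_det`, CDOM absorption `a_cdom`, all m⁻¹, plus pixel
classification flags), `lakechl` implements everything downstream:

1. **Quality masking** — an 11-bit flag vocabulary (water / cloud / cloud
   buffer / cloud shadow / cirrus / processor out-of-scope and
   out-of-range bits / shoreline-and-shallow-water buffer). A pixel is
   valid iff both "+" flags are raised and none of the nine "−" flags is.
2. **Geometric exclusion** — a 120 m inward shoreline buffer (mixed
   land–water pixels, adjacency effects) plus removal of lake areas
   shallower than the 95% quantile of Secchi-depth measurements (bottom
   reflectance).
3. **Match-up selection** — an in-situ sample is paired with a scene when
   acquired within 24 h; the 3×3 macropixel (180 m × 180 m at 60 m pixels)
   centred on the station must have ≥ 6 valid pixels whose population
   standard deviation is < 20% of their median; the satellite value is the
   mean of the valid pixels.
4. **Regional calibration** — the chlorophyll-from-IOPs model

   `Chl = A (a_pig + B (a_det + a_cdom))^C`,  canonical (A, B, C) = (21, 0.77, 1.04),

   refit against match-ups by log-scale nonlinear least squares, with r²
   and RMSE reported on the linear scale.
5. **Patchiness mapping** — for every scene with ≥ 50% of the valid-water
   pixels unflagged, pixels within ±5% of the lake-wide median, lower
   quartile or upper quartile are flagged; frequencies accumulated over the
   series give a 3-band percent composite. Pixels that are often near the
   median are the representative places to sample.

A synthetic-scene generator with known ground truth (planted multiplicative
patchiness pattern, lognormal noise, cloud discs, flag noise, in-situ
surveys with time offsets and measurement error) makes the whole chain
testable end to end with no download.

## Worked example

```r
library(lakechl)
cfg <- pipeline_config(seed = 1, n_scenes = 40)  # all defaults as above
run_pipeline("all", cfg, "demo_out")
```

prints (log counts from an actual run):

```
simulate: 40 scenes, 120 in-situ samples, 716 lake pixels [73b1de33]
mask: 500 of 716 lake pixels valid water (exclusion depth 7 m)
matchup: 120 candidates, 84 passed (rejected: insufficient_valid=36)
calibrate: n=84 r2=0.895 rmse=1.48 A=20.428 B=0.8245 C=1.0177
patchmap: 35 of 40 scenes met the coverage rule
```

Reading the log: a circular 900 m-radius synthetic lake on a 50×50 grid of
60 m cells has 716 lake pixels, of which 500 survive the 120 m shoreline
buffer and the Secchi-based shallow-water exclusion (7 m this run). 40
scenes with 20% cloud cover and three deep-water stations yield 120
time-window candidates; 36 lose their macropixel to clouds, 84 pass the
full QC. Refitting the calibration on those noisy match-ups recovers
coefficients near the canonical (21, 0.77, 1.04) — the truth used to build
the scenes — with r² = 0.90 and RMSE = 1.5 mg m⁻³ against in-situ values
carrying 10% measurement noise. 35 of 40 scenes meet the ≥ 50% coverage
rule and enter the 3-band frequency composite written alongside the other
artifacts (`demo_out/chl_spatial_variability_*.asc` + `.json` sidecar).

The same stages are scriptable one at a time:

```sh
Rscript inst/cli/lakechl.R --stage matchup --out out --seed 2 --n-scenes 6
```

## File formats

All artifacts are plain text: a documented single-file scene-series
container (JSON header with CF-style `flag_masks`/`flag_meanings`, full
double precision grids), ESRI ASCII grids for rasters, GeoJSON for
polygons, CSV (`lake, station_id, lat, lon, datetime, chl_mg_m3, source`)
for in-situ samples. See the methods vignette (`vignettes/`) for the model
description, parameter rationale and known limitations.
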