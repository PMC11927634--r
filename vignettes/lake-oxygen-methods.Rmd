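---
title: "Methods: reconstructing and attributing lake surface dissolved oxygen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing and attributing lake surface dissolved oxygen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lakedo)
```

## The problem

Surface dissolved oxygen (DO, mg/L) in lakes integrates two controls. The
physical control is solubility: the equilibrium concentration DOsol set by
water temperature and barometric pressure, which falls as water warms. The
biological control is the departure from saturation (DO SP, in percent):
photosynthesis pushes surface water above 100% saturation, respiration and
decomposition pull it below. Long in situ DO records exist for only a small
fraction of the world's lakes, so `lakedo` reconstructs DO from variables
that are observable everywhere — daily climate forcing, satellite
water-colour features, and static geography — and then decomposes what the
reconstruction shows: long-term trends, the split between solubility and
eutrophication, the imprint of atmospheric heatwaves, low-oxygen stress, and
scenario projections.

Because the package is developed and tested without any satellite or
reanalysis downloads, a synthetic-lake generator is a first-class module: it
produces cohorts with known ground truth whose statistical structure mirrors
what the real analysis assumes, and every downstream stage is validated by
recovering that ground truth.

## Water-colour features

Two features summarise a multispectral water-leaving reflectance sample.

The **floating algae index** is the NIR reflectance height above the linear
red–SWIR baseline,

$$\mathrm{FAI} = R_{nir} - R_{red} - (R_{swir}-R_{red})\frac{859-645}{1240-645},$$

with band centres fixed at 645/859/1240 nm. It is linear and homogeneous in
the bands (`fai()` tests assert both), and rises with surface phytoplankton
biomass; we use it as the eutrophication proxy throughout.

The **chromaticity hue angle** maps blue/green/red reflectance through the
CIE tristimulus transform to chromaticity coordinates $(x, y)$ and takes the
angle of $(x-0.33,\, y-0.33)$ around the white point, plus a degree-5
polynomial correction $\Delta a$ in $a/100$; the corrected angle is
$a' = a - \Delta a$. Two conventions are ambiguous in the printed sources:
the argument order of the two-argument arctangent and the exact white point
(0.33 versus 1/3). Both are arguments of `hue_angle()`; the defaults
(numerator $x-0.33$, denominator $y-0.33$, then a +180° shift so
$a \in (0,360]$; white point 0.33) are single documented constants so either
can be swapped without touching the transform. The implementation is tested
against an independent step-by-step transcription at 1e-9 relative
tolerance, and `hue_delta(100)` = 1.2175 (the coefficient sum) pins the
polynomial.

Water identification uses NDWI = (green − NIR)/(green + NIR) with an Otsu
histogram-splitting threshold (`ndwi_mask()`); the literature the approach
derives from does not fix the band pair or the splitting rule, so the most
common realisation was adopted. Mask post-processing (`apply_water_filters()`)
removes optically shallow pixels (optical depth below 20), keeps pixels with
water occurrence above 70%, erodes one pixel inward and discards 4-connected
components under 4 pixels. Erosion and labelling use 4-connectivity — the
conservative choice for shoreline contamination — via EBImage's diamond
brush and `bwlabel`, whose 4-connectivity we verified. Matchup reflectance
uses the 3×3 window mean, accepted only when the window's coefficient of
variation is strictly below 10%; the nine pixels are treated as the full
population, so the SD uses the 1/9 divisor (`window_cv()` documents and
tests this choice).

## Oxygen physics

Solubility uses the Benson–Krause freshwater equation with the standard
USGS vapour-pressure / partial-molar-volume pressure correction and zero
salinity. The exact formulation used by the upstream analyses is not public;
Benson–Krause is the USGS standard, matches the qualitative behaviour every
downstream stage relies on (strictly decreasing in temperature, increasing
in pressure), and our implementation reproduces the USGS DOTABLES values to
within 0.02 mg/L at every integer temperature in 0–40 °C. The function is
deliberately pluggable — it is the only place physics enters.

DO SP is the signed percent departure
$100\,( \mathrm{DO} - \mathrm{DOsol})/\mathrm{DOsol}$ (positive =
supersaturation). A percent-of-saturation variant sits behind
`do_sp(type = "percent")`. Air temperature is clamped to [0, 40] °C before
solubility evaluation: frozen or near-boiling surface water is outside the
model's domain, and sub-zero air over ice tells us nothing about the water
beneath — the same reason trend analysis restricts itself to summer months.

## The retrieval model

Matchups pair an in situ surface DO observation with the climate record
within 1 hour and the water-colour record within 2 days (`build_matchups()`).
With daily forcing the 1-hour rule collapses to a same-day join; with
sub-daily timestamps it is enforced literally. Where several candidates fall
in a window the smallest absolute gap wins, ties going to the earlier record
— deterministic and auditable. Ten features enter the model: air
temperature, pressure, solar and thermal radiation, precipitation, wind
speed (computed as $\sqrt{u^2+v^2}$ from the components), FAI, hue angle,
elevation and absolute latitude.

Features are standardized and then min–max rescaled to [0, 1], both fitted
on training rows only; test rows outside the training range scale outside
[0, 1] and are left unclipped, since tree ensembles are insensitive to
monotone feature maps and clipping would silently hide covariate shift. The
production regressor is a random forest (`ranger`, seeded,
single-threaded, so fits are bit-reproducible); one gradient-boosted
alternative (`xgboost`) is retained for comparison, and no other learners
are implemented. Hyperparameters can be grid-searched (`do_model_grid()`
spans 200/500 trees, depth 10/20/unlimited, min leaf 1/5) on an internal
validation split; the pipeline default is a single 200-tree fit, which at
the cohort sizes used here is within noise of the grid winner and an order
of magnitude faster. Feature importance uses permutation importance:
impurity importance splits credit among the strongly correlated seasonal
features (solar and thermal radiation track temperature), whereas
permutation importance correctly isolates air temperature as the dominant
driver on solubility-driven cohorts, and the suite asserts that ranking as
a property.

Evaluation reports MAE, mean relative error (rows with zero observed DO are
excluded from MRE and counted), RMSE and $R^2$, and refuses test rows whose
ids appeared in training (`evaluate_do_model()` leakage guard).

## Trends, heatwaves, attribution

All long-term rates are Theil–Sen slopes of annual summer medians (Jul–Sep
north, Jan–Mar south — the ice-free windows), reported per decade, with
Mann–Kendall significance. The Mann–Kendall test uses the tie-corrected
variance and a continuity-corrected normal approximation; for tie-free
series of length ≤ 10 the exact null distribution of S (computed from
inversion-count combinatorics) replaces the approximation. At the study's
series length of 21 the approximation holds its size: 2,000 null series
reject at 4.9% for a nominal 5%. No multiple-testing control is applied
across lakes; rates and p-values are reported per lake.

A heatwave is a run of at least 5 consecutive days strictly above the
day-specific 90th percentile of the 1970–1999 baseline. Percentiles pool
each calendar day's baseline values (leap days share slot 59 of a fixed
365-slot calendar) with linear interpolation between order statistics; the
small per-day samples make the percentile rule-sensitive, which is why the
rule is documented and the pooling window is configurable (`window_halfwidth`,
default 0 as defined; ±5 days is the common smoothing alternative).
"Strictly above" implements *exceeds*; a 4-day spike is never an event, a
5-day one always is, and the detector is checked event-for-event against a
brute-force scanner.

Heatwave impact is counterfactual: DO is predicted twice on each heatwave
day, with actual temperature and with the day-specific climatological mean,
all other features held fixed. The influence intensity is the signed percent
difference normalised by the counterfactual; the long-term impact replaces
temperature on every heatwave day with the climatological mean, re-predicts
the full series, and compares means and trends, normalised by the
actual-temperature value. Two under-determined choices are fixed and
exposed: mean intensity averages over heatwave days by default (an
event-weighted option exists), and the "excluding heatwaves" scenario
substitutes the day-specific climatological mean — the same reference
temperature the instantaneous counterfactual uses, which keeps the two
measures consistent. The maximum influence intensity is the value of
largest magnitude with its sign preserved.

Attribution fits a piecewise path model per lake on 21 annual values:
standardize every variable to mean 0, SD 1, then least-squares fits of
DOsol ~ T + wind + pressure, FAI ~ T, and DO ~ DOsol + FAI. The coefficients
are standardized path coefficients; a path is called negligible below
|0.05|. The cohort summary reports 100 × the mean coefficient per path as a
signed "contribution percent" — the simplest aggregation consistent with
standardized coefficients measuring strength and direction; how the upstream
analyses collapse per-lake path models into their printed global
percentages is not fully specified, so this definition is documented and
pluggable rather than asserted against those figures.

## Stress and projection

Stress uses the 6.0 mg/L threshold below which fish growth and food intake
decline: stress frequency is the percent of time steps strictly below the
threshold at the series' native resolution (recorded in the output), and a
lake-year is stressed when its annual mean falls below it. Projections run
the fitted model over per-member scenario forcing with water-colour features
frozen at their trailing 5-year means, and summarise the ensemble as
mean ± 2 SD across members with per-member and ensemble-mean rates. No bias
correction or downscaling is applied; the mock ensemble perturbs warming
rate and seed per member.

## What the generator emulates — and what it does not

`sim_config()` defaults are the study conditions: 2003–2023 daily series
against a 1970–1999 baseline, 0.3 °C/decade warming (the observed
global-land order of magnitude), AR(1) weather noise with coefficient 0.7
and SD 2 °C (persistence realistic enough that percentile-exceedance runs
occur naturally), ~1.5 injected heatwave events per year at +4 °C lasting
5–10 days, a latent trophic state drifting 0.1 per decade, ~28.5 clear-sky
reflectance samples and 30 in situ surveys per year, 0.3 mg/L process noise
on true DO and 0.3 mg/L observation error (a typical sonde accuracy; the
source repositories do not state one). Pressure follows the barometric
formula for lake elevation; thermal radiation co-varies with air temperature
at a realistic correlation (~0.85) rather than deterministically, precisely
because near-duplicate features would distort any importance analysis. True
DO is built as
$\mathrm{DOsol}(T, P)\,[1 + g]$ with
$g = c_1 \tanh(c_2 \cdot \mathrm{trophic}) \cdot \mathrm{solar}/\mathrm{solar}_{max}$,
$c_1 = 0.15$, so supersaturation is bounded at +15% and vanishes in the
pure-saturation limit ($c_1 = 0$), where DO SP is exactly zero and the
generator's truth is recoverable analytically.

The generator does **not** emulate spatial pixel structure (lakes are point
series; the 3×3 CV filter is exercised on constructed windows), cloud or
quality flags, atmospheric correction, lake-surface water temperature
(heatwaves are defined on air temperature, as in the source analysis),
stratification or depth structure, salinity, or ice phenology beyond the
summer-months mask. Passing tests therefore demonstrate that the machinery
is correct and self-consistent under the stated statistical structure — not
that the model generalises to real MODIS/ERA5 inputs.

Two auxiliary generators serve targeted recovery experiments:
`sim_trend_cohort()` injects an exact per-decade trend into annual series
(the direct reading of "generated with a −0.05 mg/L/decade trend"), and
`sim_path_cohort()` builds annual driver/response series with known
structural weights whose implied population standardized coefficients are
computable in closed form — the recovery tests compare against those, not
against round numbers.

## Numerical choices and degenerate inputs

* Quantiles: R type 7 (linear interpolation) everywhere.
* Calendar: fixed 365-slot day-of-year; Feb 29 shares slot 59.
* Zero-variance features scale to 0.5 with a warning; zero-variance path
  variables zero their paths with a flag; an all-equal NDWI histogram yields
  an all-water mask with a warning; a 3×3 window with zero mean fails the CV
  screen with a degenerate flag.
* Theil–Sen needs 2 distinct time points, Mann–Kendall 4 values, the path
  model 10 complete years, rate correlations 3 pairs; all are validated with
  typed errors.
* Seeds: one master seed; per-lake substreams are derived arithmetically so
  cohorts are reproducible lake-by-lake and independent of generation order.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic cohorts
sized for a desktop: the oracle comparisons use 10³–10⁴ random cases; model
recovery uses ~30,000 matchups over 145 lakes; trend recovery 500 lakes ×
21 years; attribution recovery 200 replicate lakes; the end-to-end
demonstration 200 lakes × 21 years with a 200-tree forest, a 20-lake
counterfactual subsample (the counterfactual doubles every heatwave-day
prediction, so a subsample keeps that stage proportionate) and a 2-member,
2-scenario, 20-year projection sampled every 10 days. These sizes are the
package's standing demonstration conditions; all of them are configuration,
not constants.

## Known limitations

The reconstruction inherits every limitation of a feature-based regressor:
it cannot see drivers absent from its features (inflows, stratification,
under-ice dynamics), and extrapolation beyond the training envelope —
exactly what a strong warming scenario asks for — relies on the tree
ensemble's flat extrapolation, which is conservative for DO decline. The
attribution's contribution percentages are means of standardized
coefficients, not variance decompositions; they change meaning if the path
structure changes. Heatwave detection on air temperature is a proxy for
water-temperature extremes with lags the counterfactual ignores. The
Mann–Kendall test is run without autocorrelation pre-whitening; annual
summer medians are close to serially independent in the generator, but real
lake series may not be.
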