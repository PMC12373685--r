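---
title: "Quantifying lag-1 legacy effects on dryland NPP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lag-1 legacy effects on dryland NPP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(npplegacy)
```

## The problem

In water-limited ecosystems, year-to-year variation in net primary
productivity (NPP) is only weakly explained by the same year's
precipitation (PPT). One candidate explanation is a *legacy effect*:
conditions in the previous year — and in particular the previous year's
productivity, standing in for vegetation density, bud banks, litter and
nutrient carry-over — constrain or enhance what the current year can
produce. npplegacy estimates the size and sign of that lag-1 effect from
pixel-year panels of water-year PPT, temperature and partitioned NPP,
and asks how it varies along gradients of mean annual precipitation
(MAP) and vegetation structure (the herbaceous share of NPP).

## The model family

All models act on *anomalies*: a pixel's annual value minus that pixel's
own long-term mean, so every series is centred per pixel
(`compute_anomalies()`). Writing `NPPdev[x,t]` for the NPP anomaly of
pixel `x` in water year `t`, the fitted structures are:

* **eq1** — `NPPdev = alpha + sigma * PPTdev + e`: current-year PPT
  sensitivity only. `sigma` has units g C m^-2 per mm.
* **eq2** — adds `tau * lagNPPdev`: the pooled lag-1 legacy model.
  `tau` is unitless; `|tau| < 1` is the stationary regime.
* **eq3 / eq4** — per-ecoregion intercepts, PPT slopes, MAP (or
  herbaceous-fraction) main effects, lag slopes, and
  lag x MAP (or lag x herb) interactions. The interaction coefficient is
  the change in the legacy coefficient per mm of MAP (eq3, order 1e-3)
  or per unit herbaceous fraction (eq4, order 0.1–0.5).
* **eq5** — per-ecoregion lag x current-PPT interactions: how legacy
  state modifies current-year PPT sensitivity.
* **lag_ppt / lag_temp** — eq2 with lagged PPT or temperature anomalies
  as alternative legacy proxies.

Estimation is ordinary least squares (`fit_legacy()`/`fit_ols()`).
Coefficient *uncertainty* is deliberately not taken from model-based
standard errors — pixels are spatially dependent — but from the
stratified spatial block bootstrap below.

### Coding of the per-ecoregion models

The per-ecoregion models use **cell-means coding**: there is no global
intercept; the ecoregion indicator columns are the intercepts, and every
ecoregion carries its own slope for each term. A global intercept plus a
full set of ecoregion indicators would be exactly collinear (the
indicators sum to one), and a reference-level coding would make the
printed coefficients contrasts rather than the per-ecoregion effects we
want to read directly. With cell-means coding each `theta:<ecoregion>`
*is* that ecoregion's lag effect. Since the model equations' global
intercept is absorbable into the ecoregion means, the two
parameterizations describe the same model space.

Interactions use **uncentered** covariates by default so that
coefficients stay on per-mm and per-fraction scales; `center = TRUE` in
`legacy_model()` switches to centred covariates. Because the lag slope
term is always present alongside the interaction, centring changes the
printed `theta` values but not the interaction estimates.

## The stratified spatial block bootstrap

`run_bootstrap()` resamples *whole pixels* (a pixel contributes all of
its years or none) so that within-pixel temporal dependence travels with
the sample, and stratifies pixels by (ecoregion, below/above that
ecoregion's mean MAP) so every draw spans the climatic gradient. Per
iteration a fraction of each stratum (rounded, floor of one pixel) is
drawn without replacement, the model is refit, and R^2, AIC and all
coefficients are recorded; 1000 iterations with 99% percentile
confidence intervals are the study defaults. A coefficient is called
significant when its CI excludes zero. `paired_model_deltas()` fits two
nested specs to the *same* draw (first-year rows, which lack a lag, are
dropped from both models so R^2 and AIC compare identical rows) and
summarizes the distribution of differences.

Reproducibility contract: one master seed spawns one sub-seed per
iteration, so results are bit-identical regardless of execution order.
Iterations that produce a rank-deficient design are redrawn and counted;
more than 5% redraws aborts the run.

"Repeated with replacement" is ambiguous between within- and
across-iteration replacement; we sample without replacement within an
iteration and redraw independently across iterations (at sub-percent
sampling fractions the two are practically identical), with a
`replace = TRUE` switch for sensitivity checks.

## Diagnostics

* **R^2** is 1 − RSS/TSS about the response mean.
* **AIC** is `n log(RSS/n) + 2 (k + 1)` — the Gaussian profile form
  without the `n log(2*pi) + n` constant. Only AIC *differences* between
  models on the same rows are meaningful; differences under this
  convention equal those under the standard one, while *percentage*
  changes in AIC depend on the additive constant and are labelled
  convention-dependent by `compare_models()`.
* **Durbin-Watson** (`durbin_watson()`) is computed with first
  differences taken only *within* a pixel's time-ordered residuals —
  never across pixel boundaries — and pooled over pixels. Values below 2
  indicate positive lag-1 residual autocorrelation; on a legacy-bearing
  panel the PPT-only model sits well below 2 and adding the lag term
  moves the statistic close to 2.

## Pixel-wise mapping and trimming

`fit_pixel_lag()` fits the eq2 structure independently to each pixel's
own series (intercept, PPT slope, lag slope), skipping pixels with fewer
than five usable years (a guard for degenerate inputs; full-length
series are far above it) or constant predictors. For map display,
`trim_percentiles()` masks values outside the (2.5, 97.5) percentile
band. Percentiles use the `p(n+1)` plotting-position convention
(`stats::quantile` type 6): trimming counts depend on the convention,
and under this one the integers 1..100 trimmed at (2.5, 97.5) lose
exactly {1, 2, 99, 100}. Coefficient surfaces are written as plain-text
georeferenced ESRI ASCII grids (`write_ascii_grid()`), the package's
native grid format.

## Extreme-to-normal transitions

For each pixel and variable (PPT, NPP, temperature),
`extreme_transitions()` finds the years with the single largest and
smallest anomaly — the final year is excluded as a candidate because it
has no following year; ties break to the earliest year and are flagged —
and pairs them with the following year's NPP anomaly. The *normal
following year* filter keeps a transition only when the following year's
PPT anomaly is within 1 pixel-specific PPT standard deviation of zero
(boundary inclusive; 0.25 SD is the stricter sensitivity setting),
screening out back-to-back extremes and multi-year droughts or wet
runs, which this package does not model. `transition_correlation()`
reports Spearman rank correlations pooled across both directions and per
direction. Note one subtlety: the filter bounds the following year's PPT
anomaly, which does not *logically* prevent that year from being the
pixel's opposite PPT extreme when that extreme happens to be mild; the
guarantee is only that no passing successor breaches the filter
threshold.

Even without any legacy, the correlation between an extreme-year anomaly
and the next year's anomaly is not exactly zero: per-pixel centring and
selection of the extreme induce a small regression-to-the-mean effect.
The tests therefore compare the null-generator correlation against a
brute-force simulated null rather than against zero.

## The synthetic landscape generator

Real continental-scale inputs (gridded daily weather, partitioned NPP
rasters) are not required anywhere: `generate_landscape()` builds a
multi-ecoregion landscape with known truth, and every downstream stage
is validated against that truth.

The data-generating process per pixel `x` is the minimal one consistent
with a linear-positive lag-1 legacy:

```
NPPdev[x,t] = sigma * PPTdev[x,t] + tau_x * NPPdev[x,t-1] + eps[x,t]
tau_x       = tau0 + delta_map * MAP_x + delta_herb * HERB_x
```

with annual PPT gamma-distributed (right-skewed, strictly positive, CV
`1/sqrt(shape)`; shape 8 by default, i.e. CV ~ 0.35) with per-pixel mean
`MAP_x` drawn uniformly in the ecoregion's range, Gaussian annual
temperature, and Gaussian residuals `eps` whose variance is split
between a component shared by all pixels of a square spatial cluster
(default 25 pixels, `cluster_rho = 0.5`) and a pixel-specific component.
The shared component is what makes resampling whole pixels within
spatial blocks consequential. Generation fails loudly if any
`|tau_x| >= 1` (non-stationary). Series start from the stationary
marginal `N(0, (sigma^2 Var(PPT) + noise_sd^2) / (1 - tau_x^2))`, which
avoids burn-in transients; an optional burn-in mode (default 10
discarded years) exists for checking initialization insensitivity.
Absolute NPP is the ecoregion mean plus the anomaly, floored at zero
(rare at the default parameters), and partitioned so the herbaceous
groups sum to exactly `HERB_x` of the total (annual:perennial split
40:60, shrub:tree 85:15 — bookkeeping constants that affect no
estimand except the partition-sum identity).

Default parameter choices, made once:

* Five ecoregions spanning MAP ~100–600 mm and herbaceous fractions
  0.4–1.0, with mean NPP scaling at roughly 0.4 g C m^-2 per mm MAP —
  the western-US dryland regime the method targets.
* `sigma_true = 0.3` g C m^-2 per mm and `tau0_true = 0.45`, mid-range
  for observed dryland PPT sensitivities and lag coefficients.
* `noise_sd = 45` g C m^-2: at this residual level the PPT-only model
  explains ~0.3 of anomaly variance and the lag model ~0.5, the regime
  reported for real dryland panels; smaller values make every test
  trivially easy, which would overstate what passing shows.
* 36 years per pixel, matching the length of modern remote-sensing NPP
  records.

What the generator deliberately does **not** emulate: realistic spatial
covariance (shared-block noise, not variograms), disturbance processes
(fire, grazing, land-use change), multi-year drought persistence,
observation error in remote-sensing NPP, and non-Gaussian NPP residuals.
Passing tests therefore demonstrate that the estimators recover known
lag structure under a well-behaved dryland-like process — not that real
remote-sensing panels satisfy these assumptions.

## Other conventions and numerical choices

* Sample statistics use the n−1 (sample) SD/variance convention
  throughout.
* The herbaceous fraction is the mean over years of the yearly
  herbaceous share (zero-NPP years excluded), not the ratio of means;
  `herb_method = "ratio_of_means"` switches. The two differ slightly on
  variable series.
* Calendar-year NPP is paired with the water year (Oct 1 – Sep 30)
  ending in the same labelled year; incomplete edge water years are
  dropped by `water_year_aggregate()`.
* Stratum sample sizes round to the nearest integer with a floor of one
  pixel. Pixels exactly at their ecoregion's mean MAP go to the upper
  stratum.
* The per-pixel NPP-outlier screen in `apply_inclusion_filters()`
  (off by default) recomputes its ecoregion quantile on whatever panel
  it is given, so it is a one-shot rule: the label allow-list and
  minimum-years rules are idempotent, the quantile screen is not.
* Standardized fits (`standardize = TRUE`) divide every anomaly by its
  pixel's SD of the parent variable, so the lag column remains exactly
  the shifted standardized NPP series; zero-SD pixels are excluded with
  a warning.

## Problem sizes used in the shipped checks

The package's own validation runs on synthetic panels of 2,000 pixels
(400 per ecoregion) by 36 years with 200 bootstrap iterations for
recovery and model-comparison checks; 40 independent null worlds of 400
pixels with 100 iterations each for CI calibration; and 5,000 pixels
with a sampling fraction of 0.2 for the interaction-sign analyses. That
last choice departs from the headline 0.1% sampling fraction
deliberately: at desk scale, 0.1% of 2,000 pixels is two pixels per
ecoregion per iteration, far too few rows to resolve an interaction of
magnitude ~0.45 per unit herbaceous fraction, whereas the full-scale
analysis draws on the order of a thousand pixels per iteration. Scaling
the fraction keeps the number of pixels per iteration comparable to the
full-scale procedure while leaving the procedure itself unchanged.

## Known limitations

* Rank-deficient designs error rather than being repaired; collinear
  term names are reported.
* The quantile-based outlier filter is not idempotent (above).
* `aggregate_resolution()` assumes a regular grid with square cells and
  averages partial edge windows over available cells only.
* Multi-year legacies (lags beyond one year) and drought-length effects
  are out of scope; the lag-1 structure is the estimand.
* Percent changes in AIC are convention-dependent and should not be
  compared across software.
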