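# npplegacy

Legacy effects of previous-year productivity on dryland net primary
productivity (NPP).

In drylands, the current year's precipitation is a surprisingly weak
predictor of the current year's NPP. One reason is hysteresis: last
year's productivity — a proxy for vegetation density, bud banks, litter
and nutrient carry-over — constrains or enhances this year's growth.
npplegacy is an R package for ecosystem ecologists who want to quantify
that lag-1 legacy effect from pixel-year panels of water-year
precipitation (PPT), temperature and partitioned NPP.

The core statistic is the lag coefficient τ in the anomaly regression

```
NPPdev[x,t] = α + σ · PPTdev[x,t] + τ · lagNPPdev[x,t-1] + ε[x,t]
```

where anomalies (`*dev`) are deviations from each pixel's own long-term
mean. τ > 0 means productive years follow productive years (a
linear-positive legacy); τ < 0 would mean overshoot and compensation.
Richer model structures let τ vary by ecoregion and interact with mean
annual precipitation (MAP), the herbaceous fraction of NPP, or
current-year PPT. Uncertainty comes from a stratified spatial block
bootstrap — whole pixels are resampled within (ecoregion × wet/dry side
of the ecoregion's mean MAP) strata — rather than from model-based
standard errors, because pixels are spatially dependent.

The package covers the full workflow:

* `generate_landscape()` — synthetic multi-ecoregion dryland panels with
  a *known* lag-1 data-generating process, so every estimator can be
  checked against ground truth;
* `read_panel()`, `write_fixture()`, `apply_inclusion_filters()`,
  `aggregate_resolution()` — tabular and plain-text raster (ESRI ASCII
  grid) IO, pixel screening, resolution aggregation;
* `water_year_aggregate()`, `compute_climatology()`,
  `compute_anomalies()`, `standardize_anomalies()` — water-year
  aggregation and anomaly construction;
* `fit_legacy()` — OLS fits of the model family (`eq1`–`eq5`,
  `lag_ppt`, `lag_temp`) returning a `legacy_fit` with `print`,
  `summary`, `coef`, `predict`, `residuals`, `simulate` and `plot`
  methods, plus R², a documented-convention AIC and a panel
  Durbin-Watson statistic;
* `run_bootstrap()`, `paired_model_deltas()` — the block bootstrap and
  paired ΔR²/ΔAIC model comparison;
* `fit_pixel_lag()`, `trim_percentiles()`, `rasterize_coefficients()` —
  pixel-wise τ maps;
* `extreme_transitions()`, `transition_correlation()` — NPP anomalies in
  the year following each pixel's wettest/driest, most/least productive
  (and hottest/coldest) years, with the "normal following year" PPT
  filter;
* `run_study()` / `export_summaries()` — the whole pipeline from a
  declarative YAML config (see `inst/extdata/demo_config.yaml` and the
  `inst/scripts/run_study.R` command-line wrapper).

## Worked example

Simulate 1,000 pixels across five ecoregions with a true legacy
coefficient of 0.45, then recover it:

```r
library(npplegacy)

cfg  <- synthetic_config(n_pixels_per_ecoregion = 200, n_years = 36,
                         sigma_true = 0.3, tau0_true = 0.45, seed = 42)
land <- generate_landscape(cfg)
anom <- compute_anomalies(land$panel)
clim <- compute_climatology(land$panel)

fit_legacy(anom, clim, "eq2")
#> Legacy-effect OLS fit (eq2)
#>   n = 35000, terms = 3, dropped rows = 1000
#>   R2 = 0.5094, AIC = 265400, DW = 1.965
#> Coefficients:
#>   alpha   sigma     tau
#> 0.03826 0.29720 0.42580
```

The pooled fit recovers σ (0.297 vs a true 0.3 g C m⁻² per mm) and τ
(0.426 vs 0.45; the small shortfall is the usual finite-sample
attenuation of lag estimators on 36-year centred series). The 1,000
first-year rows carry no lag and are dropped. DW ≈ 1.97 says the lag
term has absorbed the residual autocorrelation. The bootstrap puts an
interval around τ:

```r
run_bootstrap(anom, clim, "eq2", n_iterations = 200, fraction = 0.01,
              seed = 1)
#> Stratified spatial block bootstrap: eq2
#>   iterations = 200, CI level = 0.99, seed = 1
#>  metric       mean     ci_lo     ci_hi significant
#>      r2    0.49960    0.3961    0.5932        TRUE
#>     aic 2662.00000 2602.0000 2712.0000        TRUE
#>   alpha   -0.02926   -1.2810    1.0760       FALSE
#>   sigma    0.29410    0.2539    0.3383        TRUE
#>     tau    0.42530    0.3398    0.5007        TRUE
```

The 99% CI for τ, [0.34, 0.50], excludes zero: a significant
linear-positive legacy. And the year after each pixel's most extreme
productivity years still carries that signal:

```r
tr <- extreme_transitions(anom, clim)
transition_correlation(tr[tr$variable == "npp", ])
#>    group       rho       p_value    n
#> 1 pooled 0.7643752 1.475417e-280 1462
```

A Spearman correlation of 0.76 between the extreme-year NPP anomaly and
the following "normal" year's anomaly: unproductive years beget
unproductive years, and vice versa.

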