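# fptars

First-passage-time analysis of waterfowl GPS telemetry: scale detection,
movement segmentation, utilisation-distribution sampling units, lagged
environmental covariates, and AICc selection over a mixed-model candidate
set.

## Who this is for

Movement ecologists asking whether nomadic birds (here: arid-zone
waterfowl tracked by satellite GPS) occupy wetlands in response to
*current* conditions or to *recent changes* in conditions — rainfall
pulses and vegetation green-up in the weeks before arrival.  The package
turns raw fix tables plus raster time series into a ranked set of
mixed-model hypotheses, and ships a synthetic-data generator with known
ground truth so the whole chain can be validated end to end.

## The method

For a fix at position `c` on a path, the first-passage time at radius `r`
is the time the path spends inside the circle of radius `r` centred on
`c` (backward entry to forward exit, crossings interpolated exactly).
With `var_fpt(r)` the variance of `log FPT` across fixes, the population
mean of `var_fpt` peaks at the radius `r_max` where movements are
clustered — the scale of area-restricted search.  The FPT series at
`r_max` is segmented by minimising the penalized Gaussian contrast
`sum n_k log sigma_k^2` via dynamic programming, choosing the number of
segments `K_opt` as the last `K` whose standardised-contrast second
derivative exceeds `S = 0.75`.  Kernel utilisation-distribution isopleth
polygons of each segment become sampling units with response
`log(mFPT_Rmax)`; each gets 12 predictors (NDVI, mNDWI and precipitation
means over the occupancy window, their 16- and 32-day lagged differences,
temperature, elevation, site).  Thirty-six candidate random-intercept
models — current-condition ("reactive") and lagged-change ("prescient")
families — are fitted by ML and ranked by AICc with Akaike weights,
marginal/conditional R², generalized VIFs and residual semivariograms as
diagnostics.

## Worked example

```r
library(fptars)
cfg   <- sim_config(seed = 1, n_birds_per_site = 2)   # 3 sites x 2 birds x 120 d
study <- simulate_study(cfg)
run   <- run_pipeline(study$tracks, study$env, study$sites,
                      run_config(radii = fpt_radii(100, 80, 2000),
                                 bandwidth = c(200, 200), cell = 200,
                                 min_fixes = 5, k_max = 8, seed = 1))
run
#> <fpt_run>
#>   tracks: 6 in -> 6 after split -> 6 retained
#>   r_max: 180 m
#>   polygons: 109 (109 with covariates, 107 model rows)
#>   best model: 34 [PM32] (AICc weight 0.68)
head(run$selection, 3)
#>  model_id  tag                                     formula k   aicc ...
#>        34 PM32              d_ndvi_32 + d_precip_32 + site 7  22.69
#>        32 PM32 d_ndvi_32 + d_mndwi_32 + d_precip_32 + site 8  24.74
#>        30 PM32                     d_ndvi_32 + d_precip_32 5  27.85
run$best_fit
#> <fpt_fit model 34 [PM32]: n = 107, k = 7, AICc = 22.69, R2m = 0.821, R2c = 0.846>
#>          term   beta     se   lower   upper
#> 1 (Intercept)  4.580 0.0812  4.4210  4.7393
#> 2   d_ndvi_32  0.315 0.0236  0.2682  0.3609
#> 3 d_precip_32  0.360 0.0247  0.3115  0.4084
#> 4     siteMAN -0.294 0.1128 -0.5152 -0.0732
#> 5     siteSTR  0.270 0.1177  0.0393  0.5007
```

Reading the output: the detected ARS scale (180 m) equals the diameter of
the generator's intensive-search core; the top-ranked model is the
32-day-lag ("prescient") structure that generated the data; and the
z-scale coefficients 0.32 and 0.36 recover the configured effects of
green-up and rainfall change (0.30 and 0.35) within their intervals.
`summarize_tracks()` reproduces the standard per-track reporting columns
(total fixes, duration, fixes/day, segments, polygon counts, polygon area
and occupancy).  The published per-individual summary of the two-species
study this pipeline mirrors is available as
`waterfowl_tracking_summary()`.

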