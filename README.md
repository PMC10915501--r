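# knotflight

Departure timing of shorebird relocation flights from high-resolution
regional tracking data.

Red knots (*Calidris canutus islandica*) overwintering in the Dutch Wadden
Sea sometimes relocate to UK estuaries — a ~250 km non-migratory flight
across the North Sea with nowhere to rest en route. Given tag
localizations from a regional reverse-GPS array, detection logs, tidal and
weather series, `knotflight` answers two questions:

1. **Which tagged birds departed westward?** A rule-based classifier
   (detection gap ≤ 2 h after the last fix, last fix outside the core
   tracking area, a straight final 20 min of track with every turn < 90°,
   and a westward final segment over the sea), with explicit exclusion of
   pass-through tracks whose take-off was never observed, plus
   cut-off-date accounting of season-level departure proportions.
2. **What conditions do they select at take-off?** A use–availability
   resource selection function over *time*: each departure (used time,
   weight 1) is contrasted with 30 available times (weight 1000) drawn
   from the preceding 96 h, and a binomial GAM with logit link is fitted:

   ```
   logit P(use) ~ wind_assist + cloud + Δpressure + rain + year
                  + s(min_to_sunset) + s(min_to_hightide)
   ```

   with penalized cubic regression spline smooths (k = 10, GCV). The
   scaled selection curves are exp(partial predictor without intercept),
   min–max scaled to [0, 1]; smooth peaks get percentile confidence
   intervals from a case bootstrap by event. Wind assistance is the
   full-drift along-track wind component `U·cos(θ_to − track bearing)`.

The package also ships a synthetic-data generator (tracks, detections,
tide, weather, cloud, and departure times drawn from a *known* selection
function), so the whole pipeline is verifiable with ground truth and no
field data. Everything is tidyverse-shaped: data frames in, tibbles out,
`tidy()`/`glance()` for fits, `autoplot()` for selection curves.

## Worked example

Simulate a season of departures under a known selection function, build
the used/available design, and fit the RSF:

```r
library(knotflight)
library(tibble)

start <- as.POSIXct("2019-08-15", tz = "UTC")
end   <- as.POSIXct("2019-11-15", tz = "UTC")
env   <- sim_env(start - 5 * 86400, end + 86400, seed = 11)
grid  <- seq(start, end, by = 600)

truth  <- true_selection()   # wind +0.3/ms, cloud -0.2/okta,
                             # peaks +108 min sunset, -238 min tide
dep    <- sim_departure_times(env, truth, 200, grid, seed = 12)
events <- tibble(tag_id = sprintf("knot%03d", seq_along(dep)),
                 departure_time = dep)

design <- build_rsf_design(events, env, n_avail = 30, seed = 13)
fit    <- fit_rsf(design)
fit
#> Departure resource-selection GAM (weighted binomial, logit link)
#>  events: 200  available: 6000
#>  linear terms: wind_assist, cloud, d_pressure, rain
#>  smooth terms: min_to_sunset, min_to_hightide  (bs = cr, k = 10, GCV.Cp)
#> # A tibble: 5 × 5
#>   term         estimate std.error statistic  p.value
#>   <chr>           <dbl>     <dbl>     <dbl>    <dbl>
#> 1 (Intercept) -11.0        0.157    -70.0   0
#> 2 wind_assist   0.314      0.0217    14.5   1.57e-47
#> 3 cloud        -0.186      0.0323    -5.75  8.88e- 9
#> 4 d_pressure   -0.133      0.0867    -1.53  1.25e- 1
#> 5 rain         -0.00412    0.0228    -0.181 8.57e- 1
```

The fitted slopes recover the generating values (+0.314 per m/s tailwind
vs +0.3 truth; −0.186 per okta vs −0.2), and the nuisance terms
(pressure change, rain), generated with zero effect, are correctly found
non-significant. The smooth peaks land near the generating clock
preferences, with bootstrap intervals:

```r
peak_estimate(fit, "min_to_sunset")    # 88  (truth 108): ~1.5 h after sunset
peak_estimate(fit, "min_to_hightide")  # -227 (truth -238): ~4 h before high tide

bootstrap_peaks(events, env, B = 30, seed = 14)
#> # A tibble: 2 × 5
#>   smooth          mean_peak ci_lower ci_upper n_success
#>   <chr>               <dbl>    <dbl>    <dbl>     <int>
#> 1 min_to_sunset        85.3     74.4     98.3        30
#> 2 min_to_hightide    -230.    -245.    -210.         30

autoplot(fit)   # scaled selection curves per covariate
```

The end-to-end driver runs the whole chain (simulate → clean → classify →
annotate → fit → report) from one configuration object:

```r
report <- run_pipeline(pipeline_config(seed = 1))
report
#> Departure pipeline run
#>  tags: 28  fixes: 128778 raw -> 128778 clean
#>  departures: 10  cut-off (q=0.95): 2019-09-07
#>  at cut-off: 10 departed vs 17 remaining (37.0% departed)
#>  ...
```

(With only 10 events the smooth terms are under-informed — peak locations
stabilise from a few dozen events; see the vignette.)

## Layout

- `R/` — simulator (`sim_*`), track cleaning (`filter_*`,
  `preprocess_tracks`), classifier (`criterion_*`,
  `classify_departures`), covariates (`annotate_times`, `sunset_time`,
  `find_high_tides`, `wind_assistance`), RSF (`build_rsf_design`,
  `fit_rsf`, `rsf_curve`, `peak_estimate`, `bootstrap_peaks`,
  `sensitivity_n_available`), I/O (`read_/write_*`), driver
  (`run_pipeline`).
- `vignettes/departure-selection.Rmd` — the model, its assumptions, and
  every design decision taken where the methods left room.
- `tests/testthat/` — unit, property and acceptance suites (all fixtures
  generated in code).
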