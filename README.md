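# sealsearch

Benthic-foraging seals — Hawaiian monk seals are the motivating case —
search for cryptic prey by inverting into a head-down posture on the sea
floor. `sealsearch` turns raw animal-borne motion-sensor streams into a
classification of *searching* (foraging) dives and a model of what drives
them:

1. **Kinematics** — split tri-axial acceleration into static (gravity) and
   dynamic parts with a 2 s moving average; compute ODBA
   (`|dX| + |dY| + |dZ|`, in g), attitude (roll `= atan2(Ya, Za)`, pitch
   `= atan(-Xa / Z')` after de-rotating roll, yaw from the de-rotated
   magnetometer), and gyroscope RMS.
2. **Dive segmentation** — dives from the depth channel, with duration,
   maximum depth, bottom time (time deeper than 80% of maximum depth) and
   per-dive body-motion summaries.
3. **Search detection** — a *search event* is a contiguous run with
   pitch ≥ 70° (head-down) and depth ≤ −3 m; a dive with ≥ 1 event is a
   searching dive.
4. **Covariates** — bathymetry, shore distance, habitat (with named-polygon
   recoding of unmapped cells) and dive ratio (max depth / bathymetry),
   joined from 1 km raster grids at the interpolated dive-start position.
5. **Hierarchical model** — Bayesian logistic regression of search
   occurrence, `logit(θ_ij) = x_ij β + α_k`, with per-seal random
   intercepts `α_k ~ N(μ_α, σ_α²)`, Normal hyper-priors (precision 0.001)
   and `σ ~ U(0, 10)`, fitted by a Pólya-Gamma Gibbs sampler (C++ Devroye
   PG(1, z) draws), with split-chain Gelman–Rubin and Geweke diagnostics,
   shortest-interval HPDs, and glm-based AIC/BIC model comparison.
6. **Validation & synthetic data** — a generator that simulates both dive
   tables from the model and fully consistent raw sensor streams (square
   benthic dives, planted head-down events, stroking, noise) with known
   ground truth, plus confusion-matrix validation and parameter-recovery
   experiments against that truth.

Everything is data-frame-first and pipe-friendly: functions take tibbles
and return tibbles, fitted models have `tidy()` / `glance()` /
`autoplot()` methods, and all artefacts are written as plain CSV.

## Worked example

Simulate a small tagged deployment (3 seals × 2 trips × 20 dives at
10 Hz), run the full pipeline, and fit the model:

```r
library(sealsearch)

res <- run_pipeline(run_config(
  seed  = 2024,
  sim   = list(n_seals = 3, n_trips_per_seal = 2, n_dives_per_trip = 20,
               fs = 10),
  model = list(n_iter = 2000, burn_in = 500, n_chains = 2)),
  out_dir = "demo-run")
#> [simulate] 6 trips over a 20x20-cell grid
#> [detect] 120 dives, 229 search events
#> [fit] max R-hat 1.649
#> [done] artefacts in demo-run

dplyr::filter(res$validation$confusion, seal_id == "pooled")
#>   seal_id tp fp fn tn   n accuracy sensitivity specificity
#>    pooled 96  0  0 24 120        1           1           1

tidy(res$fit)[1:7, 1:6]
#>   term         estimate std.error conf.low conf.high spans_zero
#> 1 (Intercept)    0.684     6.92    -13.6     13.5    TRUE
#> 2 duration_min   0.172     0.484    -0.752    1.15   TRUE
#> 3 mean_odba     37.6       9.53     19.1     57.6    FALSE
#> 4 bathymetry_m  -0.0473    0.0413   -0.126    0.0356 TRUE
#> 5 dive_ratio     0.404     6.91    -13.4     14.0    TRUE
#> 6 bottom_prop    6.22      4.99     -3.45    16.1    TRUE
#> 7 shore_km       0.0912    0.116    -0.135    0.326  TRUE
```

Reading the output: the detector recovered every planted searching dive on
this deployment (pooled accuracy 1.0 over 120 dives, 96 searching / 24
not). In the model summary, `estimate` is the posterior mean in raw model
units (duration in minutes, ODBA in g, bathymetry in metres, shore
distance in km, dive ratio and bottom time as proportions);
`conf.low`/`conf.high` are the 95% highest-posterior-density bounds, and
`spans_zero` flags coefficients whose HPD crosses zero. On 120 dives only
mean ODBA is resolved away from zero — small simulated deployments are
honest about their information content; the recovery experiment below uses
3000 dives. The run directory (`demo-run/`) holds the dive table, events,
truth labels, posterior summary, validation report, a log and a JSON
manifest (config, hash, seed, versions) sufficient to reproduce the run:
rerunning with the same config gives byte-identical tables.

Useful plots: `autoplot(res$fit)` (coefficient caterpillar),
`plot_traces(res$fit)`, `plot_dive_profile(kin, events)` (depth/pitch
panels with shaded events), `plot_search_map(res$dives)`, and
`autoplot(validation_report(dep))` (detector sensitivity vs pitch
threshold).

## Repository layout

- `R/` — implementation; `src/` — C++ Pólya-Gamma sampler
- `tests/testthat/` — unit, property and acceptance suites
- `scripts/acceptance.R` — headline-quantity reproduction (above)
- `vignettes/sealsearch-methods.Rmd` — models, assumptions, numerical
  choices, and what the synthetic experiments do and do not show
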