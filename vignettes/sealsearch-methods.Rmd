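---
title: "Methods: from raw tag channels to a hierarchical model of search behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw tag channels to a hierarchical model of search behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sealsearch` implements a complete analysis chain for studying benthic
foraging in seals carrying inertial tags: raw tri-axial accelerometer,
magnetometer and gyroscope streams are turned into attitude and body-motion
metrics, dives are segmented from the pressure channel, head-down *search
events* are detected with a joint pitch/depth rule, per-dive environmental
covariates are joined from gridded rasters, and the probability that a dive
contains searching is modelled with a Bayesian hierarchical logistic
regression. This vignette records the methods, the tunable parameters, the
numerical choices, and what the synthetic-data experiments do and do not
demonstrate.

## The behavioural signal

Benthic-foraging seals target cryptic prey on the sea floor and invert into
a head-down posture to investigate, dig, or flip rocks. That posture is
visible in the accelerometer as a sustained extreme pitch. Because descent
is also near-vertical in the first few metres, the detector conditions on
depth as well: a **search event** is a maximal contiguous run of samples
with

\[ \text{pitch} \ge 70^\circ \quad\text{and}\quad \text{depth} \le -3\,\mathrm{m}, \]

both comparisons inclusive, and a **searching (foraging) dive** is a dive
containing at least one event. The depth gate — not a descent-phase
exclusion — is what keeps the initial vertical drop out of the event set;
the simulator mirrors this by keeping descent pitch above threshold only in
the top ~2 m and just below threshold (62 degrees by default) for the rest of the
descent. Both thresholds, a minimum event duration (default 0 s: any peak
counts), and a pitch sign flip for backwards-mounted tags are exposed as
arguments.

Depth is carried as *negative* metres below the surface throughout, so the
threshold reads literally; readers accept positive-down records behind a
flag, and the sign normalization is idempotent.

## Kinematics

* **Gravity separation.** A centred moving average over 2 s (window
  configurable) estimates the static (gravity) component per axis; the
  residual is dynamic. Edges use shrinking windows: no data is invented, at
  the cost of a documented bias confined to one second at each end, and
  `static + dynamic` reconstructs the raw signal exactly.
* **ODBA** (overall dynamic body acceleration) is the per-sample sum of
  absolute dynamic accelerations, in g.
* **Attitude** uses the two-step Euler de-rotation: roll
  \(= \operatorname{atan2}(Y_a, Z_a)\); after de-rotating roll,
  pitch \(= \arctan(-X_a / Z')\); the magnetometer is de-rotated by roll
  then pitch and yaw \(= \operatorname{atan2}(Y_m', X_m')\). Positive pitch
  is head-down; angles are in degrees because the detection threshold is.
  Samples whose static norm falls below 0.3 g are flagged invalid rather
  than propagated. A quaternion or Kalman/Madgwick fusion would be more
  elegant but would not be the estimator the detection rule was defined on;
  fidelity wins. Note the axis naming in field descriptions of such tags is
  sometimes inconsistent; the package implements the formulas as given and
  treats axis prose as documentation only.
* **Gyroscope RMS** over a dive combines axes as the per-sample vector norm
  before the RMS (a per-axis-RMS-then-sum mode is available); stroking
  oscillates around zero, so RMS measures average rotational energy.

## Dive segmentation

A dive is a maximal run of samples deeper than −1.5 m, extended outwards to
the adjacent surface crossings (−0.25 m) and kept when at least 8 s long.
These thresholds are conventions (typical of phocid tag processing), not
measurements, and are all configurable. **Bottom time** is the time spent at
more than 80% of the dive's maximum depth, using depth samples directly
(strict \(>\), no crossing interpolation) — results therefore carry a
one-sample tolerance, which the tests assert explicitly. Trips are delimited
by surface gaps of at least 30 min.

## Environmental covariates

Rasters are regular planar grids (1 km cells by default) carrying
bathymetry, shore distance, habitat class, and pass-through complexity
layers (slope, ruggedness, rugosity — supplied, not computed, since they
come from external GIS tooling and are not retained by model selection
anyway). Cell membership is half-open, so a point on a shared edge belongs
to exactly one cell. The dive's location is the GPS track linearly
interpolated at the dive *start*, and every covariate is read at that same
point. The **dive ratio** is maximum dive depth over local bathymetry (both
negative, so benthic dives give values near 1); ratios above 1 are possible
with raster error and are flagged, not clamped. Habitat cells mapped
`"Unknown"` that fall inside a named polygon (e.g. a deep submarine bank
beyond the reach of shallow-water habitat surveys) are recoded to the
polygon's name; surveyed classes are never overwritten.

## The hierarchical model

For dive \(j\) of seal \(k\):

\[ y_{ij} \sim \text{Bernoulli}(\theta_{ij}), \qquad
   \operatorname{logit}(\theta_{ij}) = x_{ij}\beta + \alpha_k, \]

with \(\alpha_k \sim N(\mu_\alpha, \sigma_\alpha^2)\),
\(\mu_\alpha \sim N(0, \text{precision } 0.001)\) and
\(\sigma_\alpha \sim U(0, 10)\). Covariates enter in raw model units — no
standardization — so coefficients are per minute of duration, per g of
ODBA, per metre of bathymetry, per km of shore distance, and per unit
proportion of dive ratio and bottom time. The Normal hyper-priors are read
as precision-parameterized (mean 0, precision 0.001, i.e. variance 1000):
the variance reading would give an absurdly tight prior, and the notation
comes from BUGS-family software where Normal is precision-parameterized.

**Prior on the fixed effects.** Three readings are implemented:

* `"coefficient"` (default): each \(\beta_j \sim N(\mu_j, \sigma_j^2)\)
  with its own \(\mu_j \sim N(0, 1000)\) and \(\sigma_j \sim U(0,10)\).
  Marginally this is an essentially uninformative prior per predictor.
* `"shared"`: a single \((\mu_\beta, \sigma_\beta)\) for *all* fixed
  effects. This is a shrinkage prior: coefficients are pulled towards a
  common mean. With predictors on very different scales (an ODBA
  coefficient near 9 next to a bathymetry coefficient near 0.04) and weak
  data it materially biases the large coefficients — in the recovery
  experiments below it shifts the ODBA coefficient by several posterior
  sds. It is retained as an option because it is a legitimate reading of
  the hierarchy when written without subscripts, but it is *not*
  uninformative, and the package does not default to it.
* `"independent"`: fixed \(N(0, 1000)\) priors, no hyper-parameters.

**Sampler.** Pólya-Gamma data augmentation yields a true Gibbs sampler:
\(\omega_i \sim \text{PG}(1, \psi_i)\) makes the \(\beta\) and \(\alpha\)
conditionals Gaussian; hyper-means are conjugate Normal; the bounded
hyper-sds are updated by shrinkage slice sampling within \(U(0,10)\). The
PG(1, z) draws use Devroye's exact alternating-series method, implemented
in C++ against R's RNG so that runs are reproducible under a seed. Default
settings are 3 chains of 7500 iterations with 2000 discarded as burn-in.
Chain starts are over-dispersed relative to the posterior
(\(\beta \sim N(0, 2^2)\), \(\alpha \sim N(0,1)\), \(\sigma\) uniform over
most of its support); starts drawn from the full hyper-prior (sd ≈ 32 on
the logit scale) would saturate the likelihood numerically for no
diagnostic benefit. An adaptive random-walk Metropolis-within-Gibbs
fallback (`method = "metropolis"`) adapts proposal scales towards 44%
acceptance during burn-in only, preserving detailed balance afterwards.

**Diagnostics.** Split-chain Gelman–Rubin \(\hat R\) per parameter and
Geweke z per chain (first 10% vs last 50%, spectral density at zero
estimated via an AR fit). A constant chain has no defined Geweke z and is
reported `NA`, not propagated as NaN. HPD intervals use the sorted-window
(shortest-interval) method and report whether they span zero.

**Identifiability.** With an intercept column *and* a free random-intercept
mean \(\mu_\alpha\), only the sum \(\beta_0 + \mu_\alpha\) is identified;
the posterior along the difference direction is wide and slow-mixing. This
is the literal consequence of keeping both terms. Model checks therefore
compare the *population-level* intercept (intercept plus mean random
intercept) across samplers, and the recovery experiments focus on the slope
coefficients. It also explains why a fitted table for such a model may
print no interpretable intercept at all.

**Model selection** across candidate fixed-effect sets uses
maximum-likelihood logistic fits (IRLS, via `stats::glm`, no random
effect), comparing null and residual deviance, `AIC = deviance + 2k` and
`BIC = deviance + k log n`, ranked by BIC. Non-convergent candidates are
flagged rather than dropped.

## The synthetic-data generator

Two levels, both deterministic given a master seed, with one derived RNG
stream per seal (and per trip and chain), so enlarging a simulation never
perturbs the parts already generated.

**Dive-table level** (`simulate_dive_table`) draws covariates —
bathymetry \(\sim U(-100, -5)\) m, duration (min) \(\sim\) Gamma(shape 4,
mean 5), mean ODBA (g) \(\sim\) log-normal(mean 0.15, CV 0.4), dive ratio
\(\sim\) Beta(5, 2), bottom proportion \(\sim\) Beta(6, 3), shore distance
(km) \(\sim U(0, 20)\) — and outcomes straight from the logistic model.
The default coefficient vector is the published estimate set for wild
benthic-foraging monk seals (bathymetry −0.038, shore distance 0.016,
duration 0.66, ODBA 9.077, dive ratio 2.65, bottom proportion 1.15); the
published set has no intercept, so the generator requires an explicit,
documented one (default −2.5) and \(\sigma_\alpha = 0.5\). The covariate
distributions are stand-ins matched loosely to published per-seal summary
ranges — the source reports no distributional forms — and are
config-overridable. A consequence worth stating plainly: under these exact
defaults the mean linear predictor is about +7, so roughly 99.8% of
simulated dives are searching dives. That is the stated condition and the
package does not quietly rebalance it; it does mean the data carry little
information about the weakly varying covariates, which is visible in the
honest (wide) posteriors.

**Sensor level** (`simulate_sensor_trip`) synthesises square benthic dives
over a synthetic raster: near-vertical descent and ascent (1.2 m/s), a flat
bottom at the local bathymetry, head-down search events planted inside the
bottom phase (pitch drawn from 73–88°, always below −3 m), a stroking
sinusoid on the gyroscope, extra rotational and dynamic-acceleration energy
during events, and per-channel Gaussian noise. Acceleration is the gravity
vector rotated by the planted attitude plus the dynamic terms; the
magnetometer is a fixed earth field under the same rotation; all channels
are mutually consistent, so the kinematics module recovers the planted
attitude to within a degree (outside the smoothing-filter edges) on
noiseless runs. GPS fixes are emitted at every dive start, so the covariate
join can be checked exactly against the planted bottom depths.

What the simulator does *not* emulate: hydrodynamics, prey fields,
behaviour-dependent track geometry, tag slippage, magnetometer
calibration error, Argos-style position error, or video imagery (human
annotation is replaced by the simulator's truth labels). Passing tests
therefore demonstrate that the pipeline's *operations* are correct and that
the detector recovers events whose signal structure matches the assumed
posture model — not that 70°/−3 m is optimal for any particular animal or
tag placement.

## Problem sizes and test design

The test suite runs sensor simulations at 10 Hz (the gravity filter and the
event durations in play are amply resolved; 100 Hz is the field default and
only changes cost), detector validation on a deployment of 500 simulated
dives, coefficient recovery at 6 seals × 500 dives with the full sampler
settings, and simulation-based calibration over 50 replicates at 3000 dives
each with 3 shorter chains (2400 iterations, burn-in 800) per replicate —
chains long enough that measured HPD coverage is limited by the experiment,
not by mixing. Closed-form oracles (triangular and trapezoidal bottom-time
integrals, rotation round-trips, PG moments, the 2n·ln 2 null deviance,
normal HPD quantiles) and brute-force oracles (windowed means, run-length
masks, nearest-cell search, likelihood grids) back every derived value, and
an independent JAGS fit of the identical hierarchy cross-checks the Gibbs
sampler's posterior.

## Known limitations

* The pitch metric is a threshold rule; animals searching at shallower
  body angles, or tags rotated after deployment, produce false negatives.
  The threshold sweep in `validation_report()` quantifies the sensitivity
  cost of stricter thresholds on simulated data.
* Bottom time and event durations are sample-quantized; all tolerances are
  one sample period.
* The intercept/\(\mu_\alpha\) confounding above is inherent to the model
  as written; interpret only their sum.
* Search events and prey-capture attempts are deliberately not
  distinguished.
* No spatial autocorrelation, varying slopes, WAIC/LOO, or geodesic
  coordinate handling.
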