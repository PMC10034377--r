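---
title: "Methods: a water-driven crop model and its uncertainty-aware calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a water-driven crop model and its uncertainty-aware calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(aquacal)
```

This vignette documents the modelling choices behind `aquacal`: the
simulator's functional forms and conventions, the screening and
calibration machinery, what the synthetic campaign generator does and
does not emulate, and the numerical decisions that a user extending the
package should know about.

## The simulator

`simulate_crop()` advances a daily state: thermal time, canopy cover,
layered soil water, biomass and yield. All phenology runs on growing
degree days (GDD), the average of the clamped daily temperature extremes
above the base temperature `baseT` and below the cutoff `uppT`. Thermal
time is the only clock: a calendar-day clock was considered and dropped,
because a calendar phenology would make the base temperature inert,
whereas its strong influence on a spring-sown, fast-cycling crop such as
spinach is one of the behaviours the model must express. Consequently
`baseT` acts on every developmental threshold (`plan`, `sen`, `yld`,
`mat`, `root`).

`plan` is read as the thermal time to emergence (sown crops) or to
recovered transplanting (transplants): transplanted crops display their
initial cover $CC_0 = \mathrm{ccs}\cdot\mathrm{density}/10^8$ from day 0
but only start expanding after `plan`; sown crops show no canopy until
`plan` is reached. A single parameter name, `ccs`, is used for the
seedling canopy size everywhere (one section of the source literature
spells it `css` once; that spelling is treated as a typo and not given a
separate slot).

Canopy growth uses the classic two-branch form — exponential up to
$CC_x/2$, decaying approach above — applied *incrementally*: each step
multiplies or relaxes the current cover using the effective growth
coefficient $k_{s,exp}\cdot\mathrm{cgc}$, so an arbitrary stress path is
supported while the closed forms are recovered exactly under constant
stress. Senescence switches permanently once cumulative GDD passes
`sen`, after which cover follows
$CC_{onset}\,[1 - 0.05(e^{(\mathrm{cdc}/CC_x)\,t_{sen}} - 1)]$ from the
cover at onset, floored at zero. Water-stress-induced early senescence
(depletion beyond `psen`) is applied before `sen` as a one-day decline
with the thermal step scaled by $1 - k_{s,sen}$; cover may regrow if the
stress lifts, which keeps the operator monotone in water status without
introducing hidden state.

The soil is a `tau`-drainage bucket: infiltration fills layers top-down
to saturation (what cannot be stored leaves as `excess` — runoff is not
modelled, these are flat irrigated fields), water above field capacity
percolates at $\tau(\theta-\theta_{fc})$ per day down the cascade,
evaporation is taken from the top layer only and transpiration from the
root zone in proportion to each layer's available water. Soil
evaporation uses a fixed bare-soil coefficient $k_e = 1.10$, a linear
stage-2 drying reduction
$K_r = (\theta_1 - 0.5\,\theta_{wp})/(\theta_{fc} - 0.5\,\theta_{wp})$
below field capacity, and the `evardc` reduction (%) after senescence
onset. The daily water balance must close to $10^{-6}$ mm; a violation
is a hard error, and the property tests exercise this over randomized
scenarios.

Stress coefficients follow the convex exponential response between the
upper and lower depletion thresholds (`stress_coefficient()`), linear
for stomatal closure. Aeration stress ramps linearly from 1 to 0 as the
root-zone water content rises over the last `anaer` vol% below
saturation; `anaer = 0` disables it. Cold stress on biomass is
$\min(1, \mathrm{GDD}_t/\mathrm{stbio})$ — the simplest monotone reading
of a "minimum growing degrees for full production" parameter. The
harvest-index adjustment parameters `hinc`, `hingsto`, `hipsflo` are
accepted and stored but have no effect: they were screened out as
non-influential and their functional form is not constrained by the
sources this model follows, so carrying them inert is the honest option.

The daily loop exists twice: a compiled core (`src/simulate_core.cpp`)
used everywhere, and a pure-R engine (`engine = "r"`) that mirrors it
step for step. The test suite asserts bit-level agreement on randomized
scenarios, which turns the R engine into a living specification of the
compiled one.

Soil texture classes map to representative hydraulic values
(`soil_texture_table()`: sand 36/13/5, loamy sand 38/16/7, sandy loam
41/22/10, loam 46/31/15 vol% for saturation/field capacity/wilting
point, with `tau` 0.9/0.8/0.6/0.4); explicit layer tables override the
lookup.

## Morris screening

`morris_screen()` builds classic winding trajectories on an even-level
grid with $\Delta = \ell/(2(\ell-1))$; the study setting is
$\ell = 8$, $r = 100$. Elementary effects are computed in normalized
coordinates, so a parameter's $\mu^*$ carries its range scaling. Effects
for each (variable, day) output component are divided by the mean
simulated output of that component across the design — making the
ranking comparable across variables of different units — then averaged
over observation days within a variable and finally over variables.
Days on which a variable's mean output is zero (yield before yield
formation) are excluded from the rescaling; a variable that is zero all
season is an error, not a silent drop. Per-day rescaling was chosen
over season-mean rescaling (a `rescale` flag exposes the raw option)
because it keeps early-season effects from being swamped by late-season
output magnitudes. Ties in the $\mu^*$ ranking break by parameter
declaration order, and `select_influential()` returns the shortest
prefix reaching the 95% cumulative share. Sensitivity is evaluated on
the observation schedule (weekly/biweekly), not every simulated day:
that is where the data live.

## Bayesian calibration

`calibrate_fields()` wraps a delayed-rejection adaptive Metropolis
sampler (`run_dram()`) with independent uniform priors on the bounds of
the parameter space. Study settings: 30,000 iterations, 3,000 burn-in
(a 10:1 ratio that reduced configurations keep), initial diagonal
proposal with standard deviation one tenth of each range. Adaptation
starts after $10k$ iterations, replacing the proposal covariance with
$2.38^2/k$ times the running sample covariance plus a $10^{-10}$
jitter. A rejected first-stage proposal triggers one delayed-rejection
stage with the proposal shrunk by a factor 5 and the standard two-stage
acceptance ratio; proposals outside the prior support are rejected
without a model run. Because the second stage accepts many small moves,
the combined acceptance rate typically sits near 0.8 — the `[0.1, 0.5]`
warning window refers to plain Metropolis practice and the warning is
informational. Sampler correctness is established against closed-form
oracles: a conjugate linear-Gaussian posterior, uniform prior-only
moments, and a chi-squared goodness-of-fit on Mahalanobis radii of a
correlated 2-D Gaussian target.

The likelihood is independent Gaussian per observation with one error
variance per observed variable, shared across fields and strata —  the
homoscedastic, uncorrelated error model whose assumptions
`check_error_assumptions()` tests (Brown–Forsythe Levene across
variables; pairwise Pearson correlations of residuals aligned by field
and day). Error variances are estimated, not fixed: each iteration
resamples every $\sigma^2_v$ from its conjugate inverse-gamma
conditional (prior IG(0.01, 0.01)) given the current residuals, a
Metropolis-within-Gibbs scheme; `sigma2_fixed` switches to known
variances. Simulated values are taken at the exact observation day with
no interpolation. Non-calibrated parameters stay at the supplied base
values (in the pipeline: the crop defaults, with only the
Morris-selected subset sampled).

Growing periods are labelled from the start month — April–June is
`first`, July–October is `second` — so a July start belongs to the late
cycle; the two cultivation cycles overlap in July and the start month is
the only unambiguous marker.

Chains are single (one per stratum); no multi-chain convergence
machinery is included. Diagnostics worth watching are the acceptance
rate in the run header and the posterior summaries' stability under a
longer run.

## Uncertainty propagation

`sample_posterior()` draws with replacement from the post-burn-in chain
(study value: 5000 draws); `propagate()` pushes every draw through the
simulator for each year × soil cell and summarizes the output
distribution by its mean and the *mean-centred* mean absolute deviation
$\frac{1}{n}\sum|x_i - \bar{x}|$ (`mean_abs_dev()`; the median-centred
variant is deliberately not used — the name "mean absolute deviation"
is taken at face value). Draws whose simulation fails are excluded and
counted; more than 1% failures aborts the cell, because at that point
the posterior contains structurally broken parameter combinations and a
summary would be misleading. The scenario grid keeps the study's 10 × 2
shape with generated weather under year-indexed seeds, and a fixed
reference management (field 1's start and density, calendar irrigation
of 20 mm every 10 days) so that every cell sees the same practice; the
manifest records it. Cauliflower is evaluated as yield at day 84 after
planting, spinach as biomass at day 38 after sowing — the commercial
harvest windows of each crop.

## The synthetic campaign generator

`generate_study()` emulates the monitored commercial campaign: 16
cauliflower fields (two cultivars × two periods × four), 12 spinach
fields (two cultivars × two periods × three), biweekly destructive
sampling for cauliflower and weekly for spinach with a ±1-day stagger,
canopy cover also observed on the planting day, yield at final harvest,
soil water in two layers (0–30, 30–60 cm) for cauliflower and the top
layer only for spinach. Weather comes from a seasonal sinusoid (mean
10.5 °C, amplitude 7.5 °C, warmest around day 210 — the seasonal cycle
lags the solar peak, which is what makes the July–October period warmer
than April–July) with AR(1) anomalies, a two-state precipitation
occurrence chain with gamma depths, and Hargreaves reference
evapotranspiration at 51° N floored at 0.1 mm. Soils take the texture
lookup with ±5% jitter, starting at field capacity. Spinach sowing
density is drawn per field from the commercial range
1.19–2.5 million plants ha⁻¹; cauliflower transplants are fixed at
33,000 plants ha⁻¹. Fields are irrigated by a rain-responsive rule
(20 mm whenever the past week brought less than 15 mm), reflecting the
practice on the real fields, where irrigation records were part of the
management data.

Observation noise defaults are 5 percentage points on canopy cover, 8%
relative (floor 0.05 t ha⁻¹) on biomass and yield, and 2 vol% on soil
water, truncated at physical bounds — magnitudes of the order implied
by destructive sampling on heterogeneous commercial fields. Horizons
default to 90 days (cauliflower) and 45 days (spinach).

What the generator deliberately does **not** emulate: spatial field
heterogeneity, sensor drift, image-processing artefacts in canopy cover
estimation, and — most importantly — *structural model error*: the
observations are generated by the same model family that is calibrated.
Passing recovery tests therefore demonstrate that the inference
machinery works when the model is right; they say nothing about
robustness to model misspecification on real fields. Relatedly, the
bound-truncation of generated observations and the relative biomass
noise are small departures from the homoscedastic Gaussian likelihood,
so frequentist coverage of the 90% credible intervals sits slightly
below nominal in small campaigns (empirically ~80–90% with six
fields); this is a property of calibrating a nonlinear simulator on
few fields, not of the sampler, and is documented rather than patched.

## Numerical choices and problem sizes

Degenerate inputs are rejected early with informative errors (parameter
orderings, layer hydraulic ordering, weather contiguity, observation
vocabulary and bounds). The water-balance tolerance is $10^{-6}$ mm per
day; the engines agree to ~$10^{-14}$. The canopy step inverts the
closed forms rather than differentiating them, so a zero growth
coefficient is exactly the identity. `select_influential()` treats the
cumulative share with a $10^{-12}$ slack to make 0.95-exactly cases
stable.

The test and demonstration configurations run reduced problem sizes,
chosen so the full suite exercises every stage end to end in a few
minutes: Morris with 12–25 trajectories in unit tests (100 in the
acceptance script), MCMC chains of 5,000 iterations with 500 burn-in,
500–5,000 propagated draws, and recovery studies of six single-cultivar
fields replicated ten times. The study-scale settings (r = 100; 30,000
iterations; 5,000 draws) remain the documented defaults of the
corresponding functions.

## Known limitations

- No fertility, salinity or CO₂ response; no field heterogeneity;
  no parity with any external AquaCrop executable.
- The harvest-index stress adjustments are inert pass-throughs.
- Single-chain inference; heteroscedastic or correlated error models
  are out of scope (the diagnostics report violations, the likelihood
  does not model them).
- The aeration-stress and early-senescence formulations are simple
  monotone conventions; they are screened as low-influence in this
  parameter neighbourhood, and conclusions about them should not be
  drawn from this implementation.
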