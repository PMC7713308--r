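---
title: "Inferring area-restricted search from Argos telemetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring area-restricted search from Argos telemetry: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`arstrack` implements a complete analysis chain for Argos satellite tracks of
marine megafauna: raw-fix ingestion and segmentation, a Bayesian two-state
switching state-space model that jointly estimates latent regular-interval
locations and discrete behavioural states, occupancy and residence summaries,
seascape covariate extraction, and a binomial additive mixed model of
behaviour on seascape smooths with multiple-imputation propagation of the
location/state uncertainty. The package was built around telemetry of adult
pygmy blue whales tagged in the Bonney Upwelling (Great Southern Australian
Coastal Upwelling System, GSACUS), and its synthetic-data generator emulates
those deployments so that every stage is testable without satellite data.

## The movement model

Argos fixes arrive irregularly (on average every 2.3 h in the emulated
deployments) with strongly class-dependent error, so locations and behaviour
are estimated on a regular 3-h grid by a switching first-difference
correlated random walk. Writing $x_t$ for the latent position (lon, lat in
degrees) at grid time $t$ and $b_t \in \{1, 2\}$ for the behavioural state
(1 = transit, 2 = area-restricted search, ARS),

$$x_t - x_{t-1} = \gamma_{b_t}\,(x_{t-1} - x_{t-2}) + \epsilon_t,
  \qquad \epsilon_t \sim N(0, \Sigma),$$

with move persistence $\gamma_1 > \gamma_2$ (transit is faster and
straighter; ARS slower with frequent turns) and $b_t$ a first-order Markov
chain with state-persistence probabilities $\alpha_1, \alpha_2$. Each
observation $y_i$ at time $\tau_i$ is tied to its flanking grid states by the
interpolation weight $j_i = (\tau_i - t_k)/\Delta t \in [0, 1)$:

$$y_i = (1 - j_i)\,x_k + j_i\,x_{k+1} + \eta_i,$$

where $\eta_i$ has independent t-distributed components with class-specific
scale and degrees of freedom (`argos_error_model()`). Fixing the
measurement-error table rather than estimating it follows standard practice
for this model family; the defaults are seeded from published t-distribution
calibrations of Argos errors (class-3 scales of a few hundred metres up to
roughly 2 km for class B; class Z, which has no published calibration, is set
to twice class B). These are *scale* parameters of heavy-tailed laws — tail
quantiles are several times larger. All seven classes, including Z, are
retained: the heavy-tailed measurement model absorbs poor fixes instead of a
prefilter discarding them.

$\Sigma$ is shared between behavioural states — the states differ in
persistence, not innovation scale. The generator and the model agree on this
choice; it is exposed in `model_spec()` rather than hard-coded, because some
analyses prefer state-specific diffusivity.

### Sampling

`fit_hssm()` samples the joint posterior by Metropolis-within-Gibbs:

* latent positions by systematic-scan single-site random-walk Metropolis
  (compiled code); proposal scales adapt per site during burn-in and 10% of
  proposals take a 5x wider jump so the path can hop between interpretations
  of outlier fixes;
* discrete states by an exact forward-filter backward-sampling sweep;
* $\gamma$ by conjugate truncated-normal draws under the ordering constraint
  $\gamma_1 > \gamma_2$ (enforced in every draw, so reported output never
  label-switches), $\Sigma$ by an inverse-Wishart draw, and the
  state-persistence probabilities by Beta draws, pooled across all segments
  when `hierarchy` is on (per-whale latent paths, shared movement
  parameters).

The unit tests validate the sampler against an independent JAGS
implementation of the identical model: posterior means and intervals for
$\gamma$, $\Sigma$ and the persistence probabilities agree to Monte-Carlo
precision on a shared dataset.

Bookkeeping mirrors the bsam-style regimen: per chain, `burn_in` sweeps are
discarded and every `thin`-th of the `post_burn_in` sweeps is retained, so
`retained_draws(plan) = n_chains * floor(post_burn_in / thin)`; the
publication-scale default (2 chains, 80,000 burn-in, 30,000 post-burn-in,
thin 30) retains 2000 draws. Tests and the acceptance script use reduced
plans (typically 2 chains, 3,000 burn-in, 3,000 post-burn-in, thin 5, on
3 whales x 500 steps): the plan is configuration, not part of the method, and
those sizes give converged chains (Gelman-Rubin shrink factors below 1.1) in
a few tens of seconds per fit.

### Posterior summaries

Because the state is discrete but averaged over draws, the posterior mean
state lies in $[1, 2]$; `prob_ars()` maps it to the ARS probability
`mean_b - 1`. The most probable discrete state used by the habitat model is
`mode_state = 2` iff `mean_b > 1.5`, with the tie (exactly 1.5) assigned to
transit — a declared rule, as the habitat model needs a deterministic
recoding.

### What recovery tests show — and their measured limits

On synthetic tracks with $\gamma = (0.8, 0.2)$, well-separated multi-day
dwell times (state persistence 0.98 per 3-h step), 3 whales x 500 steps and
the full seven-class error mix, the most-probable-state decoding agrees with
the simulated truth for ~89-95% of steps, and posterior means of $\gamma$,
$\Sigma$ and the persistence probabilities recover the generating values.
Frequentist coverage of the 95% credible intervals at this fixed truth,
measured over 30 independent replicates during development, was 27/30 for
each $\gamma$ component and 24/30 jointly. Two structural reasons keep joint
coverage below the naive 95%: (i) two simultaneous 95% events cover jointly
about 90% even when each is calibrated; and (ii) the generator's continuous
track is linearly interpolated to irregular observation times, so the
process restricted to the model's (offset) grid is not exactly the
first-difference CRW the model assumes — a mismatch every real deployment
shares, since animals do not move on the estimation grid. The JAGS
cross-check shows this is a property of the model under these conditions,
not of the sampler.

## The synthetic-data generator

`simulate_tracks()` draws states from the Markov chain, positions from the
switching CRW (simulated directly in lon/lat degrees, as this model family
operates; note an isotropic $\Sigma$ in degrees is mildly anisotropic in km
at mid-latitudes), then emits fixes at exponential inter-arrival times (mean
2.3 h), zeroed inside explicitly scheduled transmission gaps (explicit, not
random, so segmentation tests are deterministic), positioned by linear
interpolation between flanking true steps and perturbed by the class-specific
t errors. Defaults emulate the study system: 13 whales deployed
January-March off southern Australia, class mix dominated by A/B fixes with
5% class Z, $\gamma = (0.8, 0.2)$, $\Sigma = \mathrm{diag}(0.05^2)$
degrees^2 (giving ~3 km/h mean transit speed at 3-h steps), and multi-day
dwell times (default state persistence 0.97 per step, ~4-day mean dwell).

`simulate_seascape()` provides smooth random fields (sums of low-frequency
random Fourier modes) for the covariate suite — SST and its spatial SD, SSHa
and its SD, chlorophyll a, depth and derived bathymetry, wind, EKE, an
upwelling index. They are statistical stand-ins with plausible magnitudes
and spatial scales, not ocean physics: no advection, fronts or upwelling
dynamics. With `link = truth`, SST is warped so cells visited during ARS
are pulled toward the middle of a configurable band (default 14-17 °C),
creating a positive-control habitat in which ARS genuinely co-occurs with a
known SST range. Consequently, passing tests demonstrate that the pipeline
recovers relationships of the assumed form from data with realistic sampling
artefacts; they cannot certify performance on oceanographic structure the
generator does not produce (sharp fronts, coastline masks, seasonal cycles).

## Segmentation and track summaries

Tracks split where the interval between consecutive received fixes strictly
exceeds 48 h (a gap of exactly 48.0 h does not split), and segments with
fewer than 20 observations are dropped. All retained classes, including Z,
count toward gap timing, since all are retained upstream. Duplicate
timestamps are allowed (satellite passes can double-report); the sort is
stable.

Track metrics follow the printed per-whale summary conventions: distance is
the great-circle sum (haversine, R = 6371 km) over consecutive 3-h state
locations within segments only; duration spans first to last transmission
including gaps; mean speed divides distance by within-segment elapsed time.
With that definition 17 locations summing 203 km give 203/48 = 4.23 km/h.
Published per-whale tables with multiple gaps are not always exactly
reproducible from locations x 3 h; the within-segment definition here is
declared and the discrepancy documented rather than resolved. Days in a
region (e.g. the GSACUS preset, south of 30°S and east of 125°E) count
distinct UTC calendar days with at least one state location inside the mask
— a minimum, since gaps can only hide presence.

Occupancy grids use half-open 0.5° cells anchored at integer degrees (the
convention had to be fixed; results are insensitive at the mapped scales).
Each 3-h location contributes 1/8 of a day; per-whale surfaces are weighted
by deployment duration over the longest deployment and summed, so the grid
total equals the weighted day total exactly — a conservation law the tests
assert to machine precision, along with invariance of the total under
refinement to 0.25°.

## Seascape extraction and collinearity

`extract_covariates()` samples the nearest cell and time slice; lagged
variables (chlorophyll a, 30 days; wind, 7 days) average the field over the
window ending at the location's timestamp; wind is sampled at a nominated
fixed point rather than at the whale, matching the regional-wind convention
(the point is required configuration). Spatial-SD covariates are computed
over the cells whose centres fall within a square of the configured area
(default 100 km^2) — the area is named, the square shape is this package's
choice. Transforms (log chlorophyll, log10 SSHa_SD, log |depth|) are
applied here, once, and recorded in metadata, so the habitat model sees
final covariates. Missing extractions (outside the raster, lag window before
the raster start) yield counted NA rows; modelling drops them listwise.

`screen_collinearity()` flags pairs with $|\rho| \ge 0.8$ and variables with
VIF $\ge 3$ (VIF via regression of each column on the others, robust to
exact collinearity). Flagged scale variants of one family resolve to the
longer/larger scale — the 30-day chlorophyll lag and 100 km^2 SD windows are
kept — otherwise the later-listed variable is dropped.

## The habitat model and multiple imputation

`fit_gamm()` fits `ars ~ s(covariate_1) + ... + s(tag_id, bs = "re")` with a
binomial family and logit link via `mgcv::gam` (REML). The per-whale random
intercept is the only random term, matching the individuals-as-random-effect
design; basis size defaults to k = 10 per smooth (unstated in the source
material; mgcv penalisation makes results insensitive to k well above the
effective degrees of freedom). Smooth significance is the Wald-type
chi-square test on the spline coefficients; with `linear = TRUE` the model
collapses to plain logistic regression, which the tests exploit to match a
`glm` oracle to 1e-4.

`imputation_significance()` propagates location/state uncertainty: each of
`n_iter` refits takes one joint posterior draw (locations *and* states),
freshly extracts covariates at the drawn locations, refits, and records
which covariates reach p < 0.05; the summary is the per-covariate count of
significant refits. Draws alternate between the two retained chains — the
"100 realisations from each of the two chains" versus "re-fit 100 times"
wording is contradictory, and is resolved here as 100 total refits, 50 per
chain. A failed refit is logged and counted as non-significant, never
aborting the loop. Under a pure-noise covariate the mean significant
fraction stays near the nominal 5% (the tests bound it at 12%); under the
linked SST band with tight location posteriors it exceeds 80%. Smooth
p-values on autocorrelated telemetry rows are approximate — rows three hours
apart are not independent — so these counts rank covariate resilience to
location uncertainty rather than provide exact error rates, which is how
they should be read for real data too.

## Numerical and degenerate-input choices

* Grid construction: `floor(span/dt) + 1` states, plus one extra when the
  span is not a multiple of `dt`, so trailing fixes always have a flanking
  pair; a fix exactly on the final grid time attributes to it alone (j = 0).
* Segments spanning fewer than two time steps are rejected.
* Identical MCMC chains give a Gelman-Rubin shrink factor of exactly 1 (the
  statistic is floored at 1; the sampling-variability and df corrections
  match the coda implementation, which the tests use as an oracle). A single
  chain reports the factor as NA rather than silently.
* `summary_table()` aggregates use the sample SD (n-1); the population SD is
  reported alongside.
* Ancestry classification: at least 98% pygmy ancestry is "pure pygmy", at
  most 12% is "pure Antarctic", both bounds inclusive, anything between is
  admixed; out-of-range fractions are errors, not clamped.
* Every stochastic pipeline stage derives its seed deterministically from
  the global seed and the stage name (`stage_seed()`), so reruns are
  reproducible stage by stage.

## Known limitations

* The movement model is the two-state discrete switch; no continuous-time
  move persistence, no turn-angle rotation parameter (an extension point),
  no dive-data integration.
* Fields serialise as long-format CSV, not NetCDF; real-data users must map
  their rasters into `seascape_fields()`.
* The generator does not emulate satellite-pass clustering of fix times
  (plain exponential inter-arrivals) or within-day duty cycling.
* Occupancy uses raw weighted cell counts; no kernel/utilisation-distribution
  smoothing.
* Published real-data headline numbers (e.g. a GAMM intercept of
  1.5713 +/- 0.3301 on 4945 GSACUS locations across 19 segments) require the
  archived deployment tracks and real rasters; they are documented
  reference checks, not package tests.
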