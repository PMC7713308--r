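# arstrack

Satellite tags on marine megafauna report positions irregularly, with
kilometre-scale, heavy-tailed Argos errors, yet the scientific questions —
*where did the animal forage, and what ocean conditions was it responding
to?* — need regular, error-free locations labelled by behaviour. `arstrack`
is an R implementation of the full analysis chain used for such studies,
built around satellite telemetry of pygmy blue whales
(*Balaenoptera musculus brevicauda*) in the Great Southern Australian
Coastal Upwelling System (GSACUS):

1. **Argos ingestion and segmentation** — all seven quality classes
   (3, 2, 1, 0, A, B, Z) are retained; tracks split at transmission gaps
   exceeding 48 h and segments with fewer than 20 fixes are dropped.
2. **Switching state-space model** (`fit_hssm()`) — a Bayesian two-state
   first-difference correlated random walk on a regular 3-h grid,

   x_t − x_{t−1} = γ_{b_t} (x_{t−1} − x_{t−2}) + ε_t,  ε_t ~ N(0, Σ),

   with behavioural state b_t ∈ {transit = 1, ARS = 2} following a Markov
   chain, move persistence γ_transit > γ_ARS, and each irregular fix tied to
   its flanking grid states by a linear interpolation weight and observed
   through fixed class-specific t errors. Fitted by Metropolis-within-Gibbs
   (compiled single-site path updates, exact forward-filter
   backward-sampling for the states, conjugate parameter draws pooled
   hierarchically across whales); validated in the tests against an
   independent JAGS implementation of the same model.
3. **Behaviour and occupancy** — the probability of area-restricted search
   `p_ars = mean_b − 1`, per-whale track metrics (great-circle distance,
   within-segment mean speed, minimum days in region), and 0.5°
   weighted-day occupancy grids (each 3-h location contributes 1/8 day,
   whales weighted by deployment duration relative to the longest).
4. **Behaviour–seascape model** (`fit_gamm()`,
   `imputation_significance()`) — a binomial/logit GAMM of the most probable
   state on seascape smooths (SST, SST variability, SSHa, chlorophyll *a*
   with a 30-day lag, depth, wind at a nominated point, ...) with a
   per-whale random intercept, collinearity screening (VIF ≥ 3,
   |ρ| ≥ 0.8), and significance re-assessed over repeated joint posterior
   draws of locations and states so that location uncertainty propagates
   into the habitat inference.
5. **Synthetic data** (`simulate_tracks()`, `simulate_seascape()`) — a
   generator that emulates the deployments (13 whales, 2.3-h mean
   transmission interval, multi-day gaps, realistic class mix including Z,
   multi-day behavioural dwells) plus seascape fields in which ARS can be
   linked to a 14–17 °C SST band, giving ground truth for every stage.

## Worked example

```r
library(arstrack)

sim  <- simulate_tracks(sim_config(n_whales = 2, n_steps = 300, seed = 7))
segs <- unlist(lapply(split(sim$observations, sim$observations$tag_id),
                      segment_track), recursive = FALSE)
fit  <- fit_hssm(segs, model_spec(),
                 mcmc_plan(n_chains = 2, burn_in = 1500, post_burn_in = 1200,
                           thin = 4, seed = 42))
summary(fit)
```

```
Posterior parameter summary (600 draws, 2 segments)

                mean     sd    2.5%  97.5%
gamma_transit 0.8438 0.0304  0.7816 0.9047
gamma_ars     0.2974 0.0611  0.1729 0.4139
sigma_lon     0.0021 0.0002  0.0018 0.0026
sigma_lat     0.0023 0.0002  0.0019 0.0027
sigma_lonlat  0.0001 0.0001 -0.0002 0.0003
alpha_transit 0.9718 0.0147  0.9357 0.9913
alpha_ars     0.9761 0.0113  0.9506 0.9915

Overall mean P(ARS): 0.573

Gelman-Rubin shrink factors:
[1] 1.002 1.018 1.040 1.012 1.013 1.000 1.003
```

The generating truth here was γ = (0.8, 0.2), Σ = diag(0.05²) and state
persistence 0.97: the posterior recovers the persistence contrast between
transit and ARS, the innovation scale, and the multi-day dwell structure,
with both chains agreeing (shrink factors ≈ 1). Track summaries and the
occupancy surface follow directly:

```r
series <- as.data.frame(fit)   # tag_id, segment, timestamp, lon, lat, CI, p_ars, mode_state
do.call(rbind, lapply(split(series, series$tag_id), track_metrics,
                      mask = region_mask("GSACUS")))
```

```
      tag_id track_duration_days n_state_locations distance_km mean_speed_kmh days_in_region
sim01  sim01                37.1               298        2383           2.67             38
sim02  sim02                37.2               299        1966           2.20             38
```

Aggregates of the published 13-whale deployment table
(`pygmy_whale_summary()`) reproduce the printed headline numbers — mean
distance 4056 km (± 4072 sample SD), mean speed 3.18 km/h, mean duration
116 days, maximum distance 15,120 km:

```r
summary_table(pygmy_whale_summary())$aggregates
```

```
       track_duration_days distance_km mean_speed_kmh
min                   3.00      203.00           1.90
max                 382.00    15120.00           4.20
mean                115.54     4056.46           3.18
sd                  113.54     4072.04           0.54
```

`run_pipeline(pipeline_config(...))` chains every stage (simulate/read →
segment → fit → metrics/occupancy → extract → screen → GAMM → imputation)
with per-stage seeds derived from one global seed, and writes CSV artifacts
plus a JSON run manifest.

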