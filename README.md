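# optosec

Secretion burnout analysis and optogenetic induction control for yeast
protein production.

When a yeast strain is pushed to secrete a difficult heterologous protein,
more induction does not mean more product. Past a threshold, part of the
population transiently enters *secretion burnout* — cells accumulate
internal protein at levels more than ten-fold above the rest, mount an
unfolded-protein response (UPR), and slow their growth — while the adapted
cells divert flux from secretion to degradation. Secretion at 24 h is
therefore a non-monotonic function of induction with an interior *sweet
spot*, and the appearance of burnout ("accumulator") cells marks it.

`optosec` implements the quantitative machinery around this phenomenon for
single-cell flow-cytometry data from optogenetically induced turbidostat
co-cultures:

* **Kinetic model** — a linear three-state ODE (production intermediate
  `Prd`, protein in traffic `Trf`, secreted pool `Sec`):

  dPrd/dt = K_prd·Ind − K_prd·Prd
  dTrf/dt = K_trf·Prd − (K_sec + K_deg + K_dil)·Trf
  dSec/dt = K_sec·K_units·Trf − K_dil·Sec

  with a staged calibration: `fit_reporter_stage()` pins K_prd and K_dil on
  a non-secreted-reporter strain, `calibrate_units()` sets the
  internal-to-secreted scale, and `fit_per_induction()` fits K_trf, K_sec,
  K_deg per induction level (CMA-ES in log/logit coordinates) on the
  non-accumulator subpopulation plus the secretion endpoint.
* **Cytometry processing** — channel correction, the 1000–2000 FSC cell
  gate, size + reference normalization to relative promoter units (RPU),
  strain demultiplexing on the constitutive blue marker, pre-induction
  baseline subtraction (`process_events()`).
* **Accumulator statistics** — the mean+3σ classifier on the steady-state
  log10 distribution, Gaussian-mixture subpopulation splitting, maximal
  accumulator-fraction curves, the five-percentage-point induction and
  stress thresholds, and growth-rate inference from co-culture strain
  fractions (`accumulator_threshold()`, `split_subpopulations_gmm()`,
  `induction_threshold()`, `target_stress_level()`, `infer_growth_rate()`).
* **Feedback control** — the ±5%-duty control law that holds mean UPR at a
  target stress level (one step = 2 min 15 s of a 45-min light period),
  with closed-loop running and strategy comparison (`run_closed_loop()`,
  `compare_strategies()`).
* **Synthetic platform** — a seeded agent-based emulation of the
  turbidostat co-culture, cytometer and immunobead secretion assay
  (`scenario_config()`, `simulate_experiment()`), used to exercise and test
  every stage end to end.

## Worked example: find the sweet spot, then control to it

```r
library(optosec)

# Stage-1 calibration on a synthetic non-secreted-reporter series
rs  <- reporter_series(seed = 1)          # 45-min sampling over 24 h
fit <- fit_reporter_stage(rs$series, induction = 1, seed = 1)
round(reporter_timescales(fit), 1)
#> generation_time_min    prd_halflife_min
#>                85.9                21.7
```

The generator's physiology is a 90-min generation time and a 20-min
intermediate half-life; the fit recovers both from one noisy series.

```r
# Constant-duty characterization sweep on the simulated reactor
cfg <- scenario_config("scfv", n_cells = 1000L, dt = 0.04,
                       events_per_sample = 2000L, seed = 42)
# ... run a plant at each duty for 24 h, read secretion and stress ...
#>  duty secretion mean_upr_24h max_upr_accumulators
#>   0.0       0.1        0.000                0.000
#>   0.2     593.7        0.116                0.006
#>   0.4     730.7        0.257                0.059
#>   0.6     699.6        0.365                0.188
#>   0.8     655.9        0.447                0.335
#>   1.0     624.8        0.506                0.496
```

Secretion peaks at duty 0.4 and *falls* under full light, while the maximal
UPR-accumulator fraction climbs to half the population: the burnout
signature. The target stress is where the accumulator fraction rises five
points above basal:

```r
ts <- target_stress_level(data.frame(mean_upr = sweep$mean_upr_24h,
                                     max_fraction = sweep$max_upr_accumulators))
ts$target_stress_rpu
#> [1] 0.2331

loop <- run_closed_loop(simulator_plant(cfg, dark_h = 3),
                        ts$target_stress_rpu, duration_h = 24)
loop$endpoint_secretion
#> [1] 708
```

Holding the population at the target stress recovers 97% of the best
constant-duty secretion (730.7) without knowing the sweet spot in advance —
and 13% more than constant full induction (624.8), whose stress overshoot
feeds degradation and burnout instead of secretion.

## Documentation

The methods vignette (`vignettes/secretion-burnout.Rmd`) describes the
model and its assumptions, the staged calibration and its identifiability
conventions, the simulator's burnout mechanism and the study conditions its
defaults encode, the processing-chain ordering decisions, the numerical
choices, and the limitations of synthetic validation.
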