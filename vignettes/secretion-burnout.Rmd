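---
title: "Secretion burnout: model, statistics and feedback control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secretion burnout: model, statistics and feedback control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optosec)
```

## The problem

Driving a yeast strain to secrete a heterologous protein harder does not
always yield more protein: for hard-to-secrete products the relation between
induction and secretion is non-monotonic. When production demand exceeds the
secretory pathway's capacity, a fraction of cells transiently falls into
*secretion burnout* — they accumulate internal protein at levels an order of
magnitude above the rest of the population, mount an unfolded-protein
response (UPR), and slow their growth — while the adapted bulk of the
population diverts an increasing share of the protein to degradation instead
of secretion. The practical consequence is an *induction sweet spot*: the
lowest induction at which secretion is maximal.

`optosec` packages the quantitative machinery for finding and exploiting
that sweet spot from single-cell cytometry data of optogenetically induced
turbidostat cultures: a three-state kinetic model with a staged calibration,
an event-level processing chain, accumulator statistics, a stress-feedback
control law, and a seeded synthetic-data generator that emulates the whole
experimental platform so that every step can be exercised and tested at the
desk.

## The three-state model

The deterministic core tracks a production intermediate (`Prd`, mRNA-like),
the protein in the secretory pathway (`Trf`, measured as internal
fluorescence in relative promoter units, RPU), and the secreted pool in the
media (`Sec`):

$$\frac{d\,\mathrm{Prd}}{dt} = K_{prd}\,\mathrm{Ind} - K_{prd}\,\mathrm{Prd}$$
$$\frac{d\,\mathrm{Trf}}{dt} = K_{trf}\,\mathrm{Prd} -
  (K_{sec}+K_{deg}+K_{dil})\,\mathrm{Trf}$$
$$\frac{d\,\mathrm{Sec}}{dt} = K_{sec}K_{units}\,\mathrm{Trf} -
  K_{dil}\,\mathrm{Sec}$$

`Ind` is the normalized induction in $[0,1]$; for simulations the light duty
cycle is used directly, for real data the accessory strain's measured red
fluorescence is the induction level. Production and turnover of the
intermediate share one constant ($K_{prd}$) because they are not separately
identifiable from fluorescence; $K_{dil}$ serves both growth dilution and
media renewal because a turbidostat holds density constant, making the two
rates equal by construction. $K_{units}$ converts internal RPU to the
secreted (bead-assay) scale. The model is linear, so trajectories scale
linearly with induction and the fixed point has the closed form implemented
in `steady_state()`; `simulate_ode()` integrates with `deSolve::ode`
(lsoda, relative tolerance $10^{-10}$), segment by segment between duty
breakpoints so the step discontinuities of the light program are never
smeared by the adaptive step-size controller.

## Staged calibration

Six parameters from one noisy time series would be hopeless; the calibration
is staged so each stage pins part of the vector.

**Stage 1** (`fit_reporter_stage()`) uses a strain expressing a non-secreted
reporter, so $K_{sec}=K_{deg}=0$ and the internal signal identifies
$K_{prd}$ and $K_{dil}$ with $K_{trf}$ as a nuisance scale. Two numerical
facts shape this stage:

* With $K_{trf}$ free, the likelihood is exactly invariant under swapping
  $K_{prd} \leftrightarrow K_{dil}$ (the two-exponential rise is symmetric
  in the rates up to rescaling the amplitude). The fit resolves the
  degeneracy by the physiological labelling $K_{prd} \ge K_{dil}$: an
  mRNA-scale intermediate (half-life tens of minutes) turns over faster
  than a culture with a generation time above an hour dilutes.
* Measurement noise on fluorescence is multiplicative, and on a 45-min
  sampling grid the fast intermediate is identified almost entirely by the
  first few points of the rise. The default objective therefore uses **log
  residuals**, which weight those early small values on an equal footing
  with the plateau; plain linear least squares is available as
  `residual_scale = "linear"` and under-weights exactly the informative
  part of the series.

`reporter_timescales()` converts the fitted rates into a generation time
and an intermediate half-life in minutes; with the generator's default
physiology those are 90 and 20 minutes.

**Stage 2** (`calibrate_units()`) is a one-line linear ratio: simulate with
$K_{units}=1$ and scale so the modelled `Sec` matches a measured
secreted-reporter level.

**Stage 3** (`fit_per_induction()`) fits $K_{trf}, K_{sec}, K_{deg}$ per
protein and per induction level on the *non-accumulator* subpopulation's
median internal series (accumulators violate the model's assumptions, so
they are removed by the mixture split first) plus the 24-h secretion
endpoint. The objective is weighted least squares with

* $\sigma_{trf}$ = the series' median absolute deviation — for a series
  that has reached its plateau this estimates the measurement noise —
  floored at 1% of the signal amplitude so noise-free synthetic data do not
  degenerate the weighting;
* $\sigma_{sec}$ = 10% of the endpoint (floored analogously);
* endpoint weight $w$ = the number of time points, so the single endpoint
  carries weight comparable to the whole series.

The search runs in the coordinates $(\log K_{trf},\; \log(K_{sec}+K_{deg}),\;
\mathrm{logit}\,K_{sec}/(K_{sec}+K_{deg}))$: the time series constrains the
total outflux and the endpoint constrains the secreted share, so this
parametrization makes the two data terms nearly separable. In the raw
$(\log K_{sec}, \log K_{deg})$ coordinates the same objective has a long
curved valley along $K_{sec}+K_{deg} = \mathrm{const}$ that stalls any
local search. Rates are returned on the natural scale and are positive by
construction.

All stages optimize with CMA-ES (`cma_es()`), a standard
covariance-matrix-adaptation evolution strategy implemented in the package
(weighted recombination, cumulative step-size adaptation, rank-one plus
rank-$\mu$ covariance updates), seeded for reproducibility, default
population $4+\lfloor 3\ln n\rfloor$ and 200 generations.

## The synthetic-data generator

The generator stands in for the deposited raw data: it emulates a
turbidostat co-culture (strain of interest plus a constitutively marked
accessory strain at an initial 1:10 accessory:interest mix), automated
cytometry sampling every 45 min with 5000 events per sample, and the
immunobead secretion readout. It is first-class, tested code: the defaults
*are* the study conditions, not tuning knobs.

Each of `n_cells` (default 2000) lineages carries a static log-normal
expression factor (`expr_sigma = 0.35`, the lineage-scale gene-expression
noise that gives cytometry distributions their log-normal width), a
log-normal trafficking capacity (median 23 RPU/h, log-sd 0.6), and states
`prd`, `trf`, a fast intracellular stress signal, and the observed UPR
reporter. Per Euler step (`dt = 0.02` h):

* demand $= k_{trf}\,e_i\,\mathrm{prd}$; the requested processing flux is
  $(k_{sec,\mathrm{eff}}+k_{deg,\mathrm{eff}})\,\mathrm{trf}$, delivered up
  to an effective capacity and split between secretion and degradation in
  proportion to the effective rate constants;
* stress up-regulates degradation ($k_{deg,\mathrm{eff}} = k_{deg}(1 +
  \mathit{deg\_stress}\cdot s)$ — the ERAD induction that makes fitted
  degradation rates climb with induction), impairs secretion
  cooperatively ($k_{sec,\mathrm{eff}} = k_{sec}/(1+(\mathit{sec\_stress}
  \cdot s)^2)$), and *clogs* the machinery (effective capacity
  $= \mathrm{capacity}/(1+\mathit{clog}\cdot s)$). The clog is the burnout
  vicious cycle: a marginal overload raises stress, which shrinks effective
  capacity, which deepens the overload — a tipping point that produces the
  clearly separated high-iPOI mode rather than a smeared tail. The
  cooperative secretion impairment is what makes the *per-cell* 24-h
  secretion genuinely non-monotonic in induction; stress-boosted
  degradation alone cannot do that, because secretion flux
  $k_{sec}\,\mathrm{trf}$ stays monotone in demand no matter how fast
  degradation grows;
* growth collapses cooperatively with load, $\mu = \mu_0/(1+(\mathit{tox}
  \cdot \mathrm{trf})^3)$: non-accumulator loads leave growth essentially
  untouched while burned-out cells arrest, which a linear toxicity term
  cannot reproduce simultaneously;
* adaptation grows capacity toward
  $\mathrm{demand}\,(1+\mathit{headroom})(1+\mathit{clog}\cdot s)$ at rate
  `adaptation_rate`: the cell builds enough machinery to push its demand
  *through* the jam. A target proportional to bare demand can never clear
  the clog, and a target proportional to the realized load exactly
  self-traps (effective capacity then tracks demand and the backlog never
  drains); with `adaptation_rate = 0` the arrest is permanent and the
  lineage washes out of the reactor — the adaptation-deficient
  (HAC1-knockout-like) scenario;
* the driving stress signal is a fast low-pass of the load
  (`stress_tau = 0.18` h, a transcription-scale delay), while the
  *observed* UPR channel is a 1-h low-pass of the same signal (reporter
  maturation). The two time constants produce the documented lag between
  the internal-protein and UPR bimodality; putting the 1-h reporter lag on
  the couplings themselves delays the accumulator wave past the observed
  2–4 h window;
* the turbidostat sets the dilution rate to the population-mean growth
  rate each step (total statistical weight is conserved exactly), and the
  media pool integrates the population secretion flux minus dilution.

The burnout flag enters when a cell's requested flux exceeds its effective
capacity by a 10% hysteresis margin and leaves when it falls back below it;
the flag is internal ground truth for tests, never an observable.

The cytometer emulation resamples cells by statistical weight; forward
scatter is log-normal around 1450 (the cell gate is 1000–2000) with 5%
debris/doublets placed outside the gate; each fluorescence channel is gain
× content × relative size plus log-normal autofluorescence, with 5%
multiplicative measurement noise. GRN-B carries the internal protein of
interest, BLU-V the accessory strain's constitutive marker, ORG-G the UPR
reporter (strain of interest) or the induction reporter (accessory). The
bead emulation produces ~1000 large, high-granularity events whose GRN-B is
a blank plus a linear response (slope 120 per RPU of media concentration),
with cell-like contaminant events for the gates to remove.

Scenario presets cover the study's qualitative protein classes: `"scfv"`
(the default; burnout-prone with an interior secretion optimum), `"amylase"`
(burnout-prone but only mildly secretion-impaired, so secretion plateaus),
`"mneon"` (ample capacity, low stress, no burnout at any induction), and
`"hac1ko"` (no adaptation, reduced basal capacity; burnout is absorbing).
Nitrogen limitation and secretory inhibitors are exposed as the pure
scalings `production_scale` and `capacity_scale`.

The scFv-like defaults were chosen once so that the simulator reproduces
the platform's documented phenomenology under full induction — accumulator
fraction rising to about half the population with the wave peaking 2–4 h
after induction and resolved again by 24 h, an accumulator internal-protein
mode more than ten-fold above the non-accumulator mode, a growth-rate dip
beyond 30%, five-percentage-point accumulator appearance at intermediate
induction aligned with the secretion sweet spot, and mean stress monotone
in duty — and they are not revisited per analysis.

## Cytometry processing

`process_events()` applies, in order: per-experiment channel correction
(calibration-bead coefficients; identity by default), the closed-interval
FSC gate $[1000, 2000]$ (an inclusive reading of the gate bounds,
documented at the boundary), per-event size and reference normalization
(channel / FSC / constitutive-reference scale, yielding RPU), strain
demultiplexing on BLU-V, and pre-induction baseline subtraction. Gating
precedes demultiplexing; the marker thresholds ($6\times10^{-2}$ for
accessory, $3\times10^{-2}$ for interest) are defined on the
size-normalized RPU signal — they are dimensionless $10^{-2}$-scale
numbers, which only makes sense after normalization. Events in the dead
band between the thresholds are excluded from both strains rather than
assigned, so that neither strain's red-channel statistics are contaminated.
The baseline is the per-strain, per-channel mean over the 2 h before
induction; values may go negative after subtraction and are preserved.
Tables carry a processing-stage attribute and are never silently
re-normalized. Counts satisfy
`n_interest + n_accessory + n_unclassified = n_after_gate` exactly.

## Accumulator statistics

The classifier threshold is mean + 3 sd of a normal fitted to the **log10**
of the 24-h (steady-state, monomodal again) sample. The log domain is
chosen because cytometry distributions are approximately log-normal and the
raw 24-h distributions are strongly right-skewed; a linear-domain switch is
provided. On truly monomodal log-normal data the false-positive fraction is
the 3-sigma normal tail, $\Phi(-3) \approx 0.00135$, which the test suite
verifies at $n = 10^6$. A mixture-based heuristic warns when the
steady-state sample still carries a distinct upper mode (the classifier's
precondition); a small *lower* shoulder — a baseline-subtraction artifact —
deliberately does not trigger it, and component separations below 0.3
decades are treated as monomodal, the same rule the subpopulation split
uses.

`split_subpopulations_gmm()` fits a two-component Gaussian mixture on log10
values with `mclust`, initialized from quantile-spanning order statistics
(deterministic, and straddles any second mode). Hard assignment is by
maximum responsibility with ties going to the non-accumulator class; fits
with means closer than 0.3 decades are declared monomodal.

Induction and stress thresholds read "appearance of accumulators" as a
**net increase of five percentage points** of the maximal accumulator
fraction over the basal level, where basal is the value at the lowest
measured induction; the crossing is linearly interpolated between the
bracketing measured points and is undefined (flagged, `NA`) if never
reached. The same crossing on the mean-UPR axis is the controller's target
stress level.

`infer_growth_rate()` uses the co-culture trick: in a turbidostat the
dilution rate cancels from the strain ratio, so the log-odds of the
accessory fraction drifts at the growth-rate difference. The slope is a
centered difference over a 3-sample window, and the accessory rate defaults
to the common pre-induction rate. The estimator is exact on noise-free
exponential co-cultures.

## Feedback control

The control law is deliberately minimal: every 45-min sample (the light
period matches the sampling period), compare the population mean UPR —
mean, not median, so a plate reader could stand in for the cytometer — with
the reference; step the duty up by 0.05 if below, down by 0.05 if at or
above (a tie counts as above: conservative on stress), clip to $[0,1]$.
One step is 2 min 15 s of light. Control starts from darkness after a 3-h
dark baseline phase. A missing measurement holds the duty. For any static
monotone plant the loop converges to a limit cycle of at most two steps
around the reference's preimage; the duty is bounded for arbitrary
measurement sequences. Simple clipping is used at the saturations (no
anti-windup): with a bounded single-step actuator there is no integrator
state to wind up.

`simulator_plant()` closes the loop against the agent-based reactor through
the full measurement chain (acquisition, gating, RPU, baseline), omitting
the accessory strain as the wet-lab control experiments do (one red channel
means the accessory's red reporter would contaminate the UPR signal).
`compare_strategies()` runs feedback and constant-duty strategies on
identically-seeded plants and tabulates the mean UPR over the final 8 h
(11 samples), the endpoint secretion, and the maximal UPR-accumulator
fraction.

## Numerical choices, problem sizes, degenerate inputs

* ODE tolerances: `rtol = 1e-10`, `atol = 1e-12`; closed-form steady state
  agrees with long-horizon integration to $10^{-4}$ relative over random
  parameter draws (a property test).
* Euler step `dt = 0.02` h (must be $\le 0.05$; larger steps are rejected
  rather than silently unstable).
* CMA-ES: seeded; the caller's RNG state is restored on exit; best-so-far
  objective is non-increasing by construction and tested.
* Degenerate inputs fail loudly: flat reporter series (non-identifiable),
  empty snapshots, non-positive correction coefficients, all-contaminant
  bead samples, saturated co-culture fractions (series truncated with a
  warning), missing secretion endpoints (time-series-only fit with
  `Ksec`/`Kdeg` flagged non-identifiable).
* Test and verification problem sizes are deliberately desk-scale: full
  simulator runs use 1000–2000 lineages with 2000–5000 events per sample;
  reporter-fit recovery is assessed as the median over 20 seeded
  replicates; classifier calibration uses $10^6$ draws; the dose–response
  sweep uses an 11-point duty grid. These sizes are the package's own
  verification conditions.

## What passing tests do and do not show

The generator reproduces the statistical structure the analysis relies on —
log-normal channels, transient bimodality with a tipping-point mechanism,
growth depression coupled to accumulation, co-culture composition drift,
linear bead response — but it is a phenomenological stand-in, not a fitted
digital twin: no ER compartmentalization, no mRNA-level stochasticity, no
cell cycle, lineage noise is static, and the optogenetic dose–response is
taken as linear in duty. Passing the suite therefore demonstrates that the
*analysis machinery* is correct and calibrated on data with the assumed
structure, not that the simulator's rate constants describe any particular
strain. On real data the channel-correction coefficients, RPU references,
bead gates and protein scale factors are experiment-specific configuration
inputs, and the identity defaults used for synthetic data must be replaced.
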