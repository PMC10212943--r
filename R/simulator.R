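#' Simulator configuration
#'
#' Parameters of the agent-based emulation of the experimental platform: a
#' turbidostat co-culture of the strain of interest with a constitutively
#' marked accessory strain (initial 1:10 interest:accessory... accessory is
#' the minority: initial accessory fraction 1/11), automated cytometry
#' sampling every 45 min with 5000 events per sample, and an immunobead
#' readout of secreted protein in the media.
#'
#' Per-cell physiology: the production intermediate and the protein in
#' traffic follow the secretion model rates, but the per-cell outflux
#' (secretion + degradation) saturates at a per-cell trafficking capacity
#' drawn from a log-normal distribution. Cells whose production demand
#' exceeds their capacity accumulate protein, mount stress (UPR reporter, a
#' first-order low-pass of the traffic load with ~1 h time constant), grow
#' slower, and recover as adaptation raises their capacity — the transient
#' "secretion burnout" subpopulation. Stress also up-regulates active
#' degradation, which is what makes the secretion dose–response of
#' burnout-prone proteins non-monotonic.
#'
#' @param n_cells Number of simulated lineages (statistical weight carriers);
#'   cytometry events are resampled from these.
#' @param mu0 Pre-induction growth rate, per hour (default 0.4).
#' @param accessory_ratio Initial accessory-strain fraction (default 1/11,
#'   from a 1:10 accessory:interest inoculum; 0 omits the accessory strain,
#'   as in the control experiments).
#' @param kprd Intermediate turnover rate, per hour (20-min half-life).
#' @param ktrf Translation/translocation rate, per hour.
#' @param ksec,kdeg Baseline secretion and degradation rate constants, per hour.
#' @param capacity_median,capacity_sigma Median (RPU/h) and log-sd of the
#'   per-cell trafficking-capacity distribution.
#' @param expr_sigma Log-sd of the static per-cell expression factor
#'   (lineage-scale gene-expression noise); sets the width of the log-normal
#'   fluorescence distributions the cytometer sees.
#' @param adaptation_rate Rate (per hour) at which capacity is up-regulated
#'   toward the demand; 0 emulates an adaptation-deficient (HAC1-knockout)
#'   strain that never recovers from burnout.
#' @param adaptation_headroom Fractional overshoot of the adaptation target
#'   above the demand; without headroom a burned-out cell approaches but never
#'   clears its deficit.
#' @param tox Load-toxicity coefficient (inverse RPU): growth =
#'   mu0 / (1 + (tox * trf)^3), so growth halves at a traffic load of
#'   1 / tox and collapses beyond it.
#' @param deg_stress Stress-coupled degradation gain: effective kdeg =
#'   kdeg * (1 + deg_stress * upr) (the ERAD up-regulation that makes fitted
#'   degradation rates climb above the accumulator-appearance threshold).
#' @param sec_stress Cooperative secretion-impairment gain: effective ksec =
#'   ksec / (1 + (sec_stress * upr)^2); at high stress the secretory route
#'   itself is inhibited, which is what turns the 24-h secretion
#'   dose-response of burnout-prone proteins non-monotonic.
#' @param upr_gain,upr_tau Gain and time constant (h) of the UPR reporter
#'   low-pass on the traffic load.
#' @param stress_tau Time constant (h) of the intracellular stress signal that
#'   drives degradation, secretion impairment and clogging; much shorter than
#'   the reporter maturation lag `upr_tau`.
#' @param burnout_margin Hysteresis margin of the burnout flag: a cell enters
#'   burnout when its requested secretory flux exceeds capacity * (1 + margin)
#'   and leaves when the flux falls back below capacity.
#' @param clog Stress-clogging gain: the effective processing capacity is
#'   capacity / (1 + clog * upr), the vicious cycle that turns a marginal
#'   overload into a runaway secretion burnout (0 disables).
#' @param production_scale Scales the production demand (nitrogen-limitation
#'   knob; 1 = standard media).
#' @param capacity_scale Scales all per-cell capacities (tunicamycin knob;
#'   1 = no secretory inhibition).
#' @param sec_slope Media-to-bead fluorescence slope of the bead assay.
#' @param sampling_min Cytometry sampling period in minutes (default 45).
#' @param events_per_sample Cytometry events recorded per sample (default 5000).
#' @param noise_cv Multiplicative measurement noise CV on fluorescence channels.
#' @param dt Euler step in hours (must be <= 0.05).
#' @param seed Integer seed; every stochastic draw of the simulator flows from it.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_cells = 2000L,
                       mu0 = 0.4,
                       accessory_ratio = 1 / 11,
                       kprd = 60 * log(2) / 20,
                       ktrf = 16,
                       ksec = 7,
                       kdeg = 1.8,
                       capacity_median = 23,
                       capacity_sigma = 0.6,
                       expr_sigma = 0.35,
                       adaptation_rate = 0.3,
                       adaptation_headroom = 0.2,
                       tox = 0.25,
                       deg_stress = 3,
                       sec_stress = 4.5,
                       upr_gain = 0.3,
                       upr_tau = 1.0,
                       stress_tau = 0.18,
                       burnout_margin = 0.1,
                       clog = 2.5,
                       production_scale = 1.0,
                       capacity_scale = 1.0,
                       sec_slope = 120,
                       sampling_min = 45,
                       events_per_sample = 5000L,
                       noise_cv = 0.05,
                       dt = 0.02,
                       seed = 1L) {
  cfg <- as.list(environment())
  pos <- c("mu0", "kprd", "ktrf", "capacity_median", "capacity_sigma",
           "expr_sigma",
           "adaptation_headroom", "production_scale", "capacity_scale",
           "sec_slope", "sampling_min", "upr_gain", "upr_tau", "stress_tau",
           "dt")
  for (nm in pos)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop("'", nm, "' must be positive")
  nonneg <- c("ksec", "kdeg", "adaptation_rate", "tox", "deg_stress",
              "sec_stress", "burnout_margin", "clog", "noise_cv")
  for (nm in nonneg)
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 0)
      stop("'", nm, "' must be non-negative")
  if (cfg$accessory_ratio < 0 || cfg$accessory_ratio >= 1)
    stop("'accessory_ratio' must be in [0, 1)")
  if (cfg$dt > 0.05) stop("'dt' must be <= 0.05 h for Euler stability")
  if (cfg$n_cells < 10L) stop("'n_cells' must be at least 10")
  cfg$n_cells <- as.integer(cfg$n_cells)
  cfg$events_per_sample <- as.integer(cfg$events_per_sample)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Scenario presets for the simulator
#'
#' Named parameterizations emulating the study's protein panel: an easily
#' handled non-secreted or secreted reporter (`"mneon"`), burnout-prone
#' hard-to-secrete proteins with a non-monotonic secretion dose–response
#' (`"scfv"`), a high-demand protein whose secretion plateaus (`"amylase"`),
#' and an adaptation-deficient variant (`"hac1ko"`).
#'
#' @param scenario One of `"mneon"`, `"scfv"`, `"amylase"`, `"hac1ko"`.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
scenario_config <- function(scenario = c("scfv", "mneon", "amylase", "hac1ko"),
                            ...) {
  scenario <- match.arg(scenario)
  base <- switch(scenario,
    # low demand, ample capacity, no stress couplings: never burns out,
    # stress stays low and secretion rises with induction
    mneon = list(ktrf = 2, ksec = 2.4, kdeg = 0.5, capacity_median = 100,
                 deg_stress = 0, sec_stress = 0, clog = 0),
    # demand ~ capacity at full induction plus stress-impaired secretion:
    # transient accumulators and an interior secretion sweet spot
    scfv = list(),
    # same burnout propensity but only mild secretion impairment:
    # secretion saturates instead of declining
    amylase = list(sec_stress = 1.6, ksec = 5),
    # adaptation-deficient (HAC1 knockout): reduced basal capacity and no
    # recovery - burnout is absorbing and burned-out cells wash out
    hac1ko = list(adaptation_rate = 0, capacity_scale = 0.2)
  )
  args <- utils::modifyList(base, list(...))
  do.call(sim_config, args)
}

lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Synthetic non-secreted-reporter time series
#'
#' Generates the first-stage calibration dataset: the internal fluorescence
#' rise of a strain expressing a non-secreted reporter under constant
#' induction, sampled on the platform's cytometry grid with multiplicative
#' log-normal measurement noise. The physiological defaults are a 90-min cell
#' generation time (`Kdil = ln 2 / 1.5` per hour) and a 20-min intermediate
#' half-life (`Kprd = ln 2 / (1/3)` per hour).
#'
#' @param induction Constant induction duty (default 1, full light).
#' @param generation_time_min Cell generation time in minutes (default 90).
#' @param prd_halflife_min Intermediate half-life in minutes (default 20).
#' @param ktrf True nuisance scale (default 1.5 RPU/h).
#' @param duration_h Sampling horizon (default 24 h).
#' @param sampling_min Sampling period (default 45 min).
#' @param noise_cv Multiplicative noise CV (default 0.05).
#' @param seed Integer seed.
#' @return List with `series` (data.frame `time_h`, `value`) and `truth`
#'   (the generating [model_params()]).
#' @export
reporter_series <- function(induction = 1, generation_time_min = 90,
                            prd_halflife_min = 20, ktrf = 1.5,
                            duration_h = 24, sampling_min = 45,
                            noise_cv = 0.05, seed = 1L) {
  kdil <- 60 * log(2) / generation_time_min
  kprd <- 60 * log(2) / prd_halflife_min
  truth <- model_params(Kprd = kprd, Ktrf = ktrf, Ksec = 0, Kdeg = 0,
                        Kdil = kdil)
  times <- seq(0, duration_h, by = sampling_min / 60)
  traj <- simulate_ode(truth, constant_induction(induction, from = 0), times)
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  value <- traj$Trf * lognormal_noise(length(times), noise_cv)
  list(series = data.frame(time_h = times, value = value), truth = truth)
}

## ---- agent-based turbidostat co-culture ------------------------------------

# measurement-model constants of the emulated cytometer; raw channel value =
# gain * content * (FSC / fsc_ref) + autofluorescence, so that dividing by
# FSC and by the reference scale (gain / fsc_ref) recovers the content in RPU
cyto_constants <- function() {
  list(
    fsc_ref = 1450,        # median cell FSC; gate is [1000, 2000]
    fsc_sdlog = 0.075,
    ssc_median = 400,
    ssc_sdlog = 0.3,
    gain = c(GRN_B = 100, BLU_V = 100, ORG_G = 100),
    autofluor = c(GRN_B = 1.0, BLU_V = 0.5, ORG_G = 0.5),  # raw-unit medians
    autofluor_sdlog = 0.4,
    blu_marker = 0.2,      # accessory constitutive mCerulean, RPU
    debris_frac = 0.05,    # doublets/debris outside the FSC gate
    bead_fsc_median = 3000,
    bead_fsc_sdlog = 0.2,
    bead_ssc_ratio = 5,    # beads: high granularity, SSC ~ ratio * FSC
    bead_blank = 30,       # raw GRN-B of a blank bead
    bead_n_events = 1000
  )
}

#' Per-channel RPU reference scales of the emulated cytometer
#'
#' The RPU conversion divides each size-normalized channel by the fluorescence
#' of a constitutive reference strain; for the emulated instrument that scale
#' is `gain / fsc_ref` per channel, so that processed values recover the
#' simulated per-cell contents.
#'
#' @return Named vector of reference scales for `GRN_B`, `BLU_V`, `ORG_G`.
#' @export
default_rpu_references <- function() {
  cc <- cyto_constants()
  cc$gain / cc$fsc_ref
}

with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

sim_init <- function(config) {
  n <- config$n_cells
  n_acc <- if (config$accessory_ratio > 0)
    max(1L, round(config$accessory_ratio * n)) else 0L
  strain <- rep(c("accessory", "interest"), c(n_acc, n - n_acc))
  draws <- with_seed(config$seed, list(
    capacity = stats::rlnorm(n, meanlog = log(config$capacity_median),
                             sdlog = config$capacity_sigma),
    expr = stats::rlnorm(n, meanlog = -config$expr_sigma^2 / 2,
                         sdlog = config$expr_sigma)))
  capacity <- draws$capacity * config$capacity_scale
  list(
    t = 0,
    strain = strain,
    prd = numeric(n),        # production intermediate (interest) / red reporter drive (accessory)
    trf = numeric(n),
    red = numeric(n),        # mScarlet: UPR reporter (interest), induction reporter (accessory)
    upr = numeric(n),
    stress = numeric(n),
    capacity = capacity,
    expr = draws$expr,
    burnout = logical(n),
    weight = rep(1 / n, n),
    media_sec = 0,
    dilution = config$mu0
  )
}

# advance the population by (t_to - t_from) hours at constant duty
sim_advance <- function(state, config, duty, t_to) {
  dt <- config$dt
  interest <- state$strain == "interest"
  mu0 <- config$mu0
  while (state$t < t_to - 1e-9) {
    h <- min(dt, t_to - state$t)
    prd <- state$prd; trf <- state$trf; upr <- state$upr
    cap <- state$capacity

    demand <- config$ktrf * state$expr * prd * config$production_scale
    # stress couplings respond to the fast intracellular stress signal; the
    # observed UPR reporter channel lags the same signal by upr_tau
    stress <- state$stress
    kdeg_eff <- config$kdeg * (1 + config$deg_stress * stress)
    ksec_eff <- config$ksec / (1 + (config$sec_stress * stress)^2)
    kout <- ksec_eff + kdeg_eff
    load <- kout * trf                   # requested processing flux
    cap_eff <- cap / (1 + config$clog * stress)
    processing <- pmin(load, cap_eff)
    sec_share <- ifelse(kout > 0, ksec_eff / kout, 0)

    # cooperative load toxicity: growth is unperturbed at normal traffic
    # loads and collapses once trf accumulates past ~1/tox
    growth <- mu0 / (1 + (config$tox * trf)^3)
    growth[!interest] <- mu0             # accessory strain is burden-free

    # burnout hysteresis on the realized secretory load: enter when the
    # requested flux exceeds capacity * (1 + margin), leave below capacity
    enter <- load > cap_eff * (1 + config$burnout_margin)
    exit <- load < cap_eff
    state$burnout <- (state$burnout | enter) & !exit
    state$burnout[!interest] <- FALSE

    # Euler updates
    state$prd <- prd + h * config$kprd * (duty - prd)
    dtrf <- demand - processing - growth * trf
    dtrf[!interest] <- 0
    state$trf <- pmax(0, trf + h * dtrf)
    state$stress <- pmax(0, stress +
      h * (config$upr_gain * trf - stress) / config$stress_tau)
    state$stress[!interest] <- 0
    state$upr <- pmax(0, upr + h * (config$upr_gain * trf - upr) / config$upr_tau)
    state$upr[!interest] <- 0
    # red channel content: interest = UPR reporter, accessory = induction
    # reporter (with the same lineage expression noise)
    state$red <- ifelse(interest, state$upr, state$expr * state$prd)

    # UPR-driven capacity expansion: cells build enough machinery to push
    # their production demand through the stress clog, with headroom, so a
    # burned-out cell eventually drains its backlog and recovers (with
    # adaptation_rate = 0 the arrest is permanent and the cell washes out)
    target <- demand * (1 + config$adaptation_headroom) *
      (1 + config$clog * stress)
    grow_cap <- interest & target > cap
    state$capacity[grow_cap] <- cap[grow_cap] +
      h * config$adaptation_rate * (target[grow_cap] - cap[grow_cap])

    w <- state$weight
    D <- sum(w * growth) / sum(w)         # turbidostat: dilution = mean growth
    state$weight <- pmax(w * (1 + h * (growth - D)), 0)
    state$weight <- state$weight / sum(state$weight)

    sec_flux <- sum(w[interest] * processing[interest] * sec_share[interest]) / sum(w)
    state$media_sec <- max(0, state$media_sec + h * (sec_flux - D * state$media_sec))
    state$dilution <- D
    state$t <- state$t + h
  }
  state
}

sim_snapshot <- function(state) {
  data.frame(
    strain = state$strain,
    expr = state$expr,
    trf = state$trf,
    upr = state$upr,
    red = state$red,
    capacity = state$capacity,
    burnout = state$burnout,
    weight = state$weight
  )
}

#' Simulate a turbidostat co-culture under an induction schedule
#'
#' Advances the agent-based population (see [sim_config()]) under the given
#' light schedule and records a population snapshot at every cytometry
#' sampling time together with the bioreactor series (dilution rate, strain
#' fractions, secreted protein in the media, burnout fraction).
#'
#' @param config A [sim_config()].
#' @param profile An [induction_profile()] defined from the simulation start
#'   (first breakpoint at or before 0), or a single constant duty.
#' @param duration_h Simulated time in hours (at least one sampling interval).
#' @return List with `snapshots` (one per sample time, each a data.frame of
#'   per-cell `strain`, `trf`, `upr`, `red`, `capacity`, `burnout`, `weight`),
#'   `times` (hours), and `reactor` (data.frame `time_h`, `dilution_rate`,
#'   `fraction_interest`, `media_sec`, `frac_burnout`).
#' @export
simulate_population <- function(config, profile, duration_h) {
  stopifnot(inherits(config, "sim_config"))
  if (is.numeric(profile) && length(profile) == 1L)
    profile <- constant_induction(profile, from = 0)
  stopifnot(inherits(profile, "induction_profile"))
  if (profile$breakpoints[1L] > 0)
    stop("profile must be defined from t = 0 (add a leading dark segment)")
  sample_h <- config$sampling_min / 60
  if (duration_h < sample_h) stop("duration must cover >= 1 sampling interval")

  times <- seq(0, duration_h, by = sample_h)
  state <- sim_init(config)
  snapshots <- vector("list", length(times))
  reactor <- data.frame(time_h = times, dilution_rate = NA_real_,
                        fraction_interest = NA_real_, media_sec = NA_real_,
                        frac_burnout = NA_real_)
  record <- function(state, i) {
    interest <- state$strain == "interest"
    reactor$dilution_rate[i] <<- state$dilution
    reactor$fraction_interest[i] <<- sum(state$weight[interest])
    reactor$media_sec[i] <<- state$media_sec
    reactor$frac_burnout[i] <<- sum(state$weight[state$burnout]) /
      max(sum(state$weight[interest]), 1e-12)
    snapshots[[i]] <<- sim_snapshot(state)
  }
  record(state, 1L)
  for (i in seq_along(times)[-1L]) {
    # integrate segment-by-segment across any duty change inside the interval
    bp <- profile$breakpoints
    cuts <- bp[bp > times[i - 1L] & bp < times[i]]
    edges <- c(times[i - 1L], cuts, times[i])
    for (k in seq_len(length(edges) - 1L))
      state <- sim_advance(state, config, induction_at(profile, edges[k]),
                           edges[k + 1L])
    record(state, i)
  }
  list(snapshots = snapshots, times = times, reactor = reactor)
}

## ---- measurement emulation --------------------------------------------------

#' Emulate cytometry acquisition of a population snapshot
#'
#' Draws `events_per_sample` events from a population snapshot (sampling cells
#' with replacement proportional to their statistical weight) and produces raw
#' cytometer channel values: forward/side scatter log-normal around the cell
#' size, fluorescence equal to gain x content scaled by relative cell size
#' plus log-normal autofluorescence, and a configurable fraction of
#' debris/doublet events falling outside the FSC cell gate. The GRN-B channel
#' carries the internal protein of interest, BLU-V the accessory strain's
#' constitutive marker, and ORG-G the UPR reporter (strain of interest) or the
#' induction reporter (accessory strain).
#'
#' @param snapshot Per-cell data.frame from [simulate_population()].
#' @param config A [sim_config()] (noise and event-count settings).
#' @param time_h Sample time stamp written into the event table.
#' @param reactor_id Reactor label written into the event table.
#' @param seed Integer seed; the draw is bit-reproducible under it.
#' @return A raw `EventTable` data.frame with columns `time_h`, `reactor_id`,
#'   `FSC`, `SSC`, `GRN_B`, `BLU_V`, `ORG_G`.
#' @export
emulate_cytometry <- function(snapshot, config, time_h = 0,
                              reactor_id = "R1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(snapshot) || nrow(snapshot) == 0L)
    stop("empty snapshot")
  cc <- cyto_constants()
  n <- config$events_per_sample
  with_seed(seed, {
    idx <- sample.int(nrow(snapshot), n, replace = TRUE,
                      prob = snapshot$weight)
    cells <- snapshot[idx, ]
    debris <- stats::runif(n) < cc$debris_frac
    fsc <- stats::rlnorm(n, log(cc$fsc_ref), cc$fsc_sdlog)
    # debris small, doublets large: outside the [1000, 2000] cell gate
    n_deb <- sum(debris)
    if (n_deb > 0) {
      small <- stats::runif(n_deb) < 0.5
      fsc[debris] <- ifelse(small,
                            stats::runif(n_deb, 200, 950),
                            stats::runif(n_deb, 2100, 3500))
    }
    ssc <- stats::rlnorm(n, log(cc$ssc_median), cc$ssc_sdlog)
    content <- cbind(
      GRN_B = ifelse(cells$strain == "interest", cells$trf, 0),
      BLU_V = ifelse(cells$strain == "accessory", cc$blu_marker, 0),
      ORG_G = cells$red
    )
    content[debris, ] <- 0
    rel_size <- fsc / cc$fsc_ref
    raw <- sapply(colnames(content), function(ch) {
      signal <- cc$gain[[ch]] * content[, ch] * rel_size *
        lognormal_noise(n, config$noise_cv)
      autofl <- cc$autofluor[[ch]] *
        stats::rlnorm(n, 0, cc$autofluor_sdlog) * rel_size
      signal + autofl
    })
    data.frame(time_h = time_h, reactor_id = reactor_id,
               FSC = fsc, SSC = ssc,
               GRN_B = raw[, "GRN_B"], BLU_V = raw[, "BLU_V"],
               ORG_G = raw[, "ORG_G"])
  })
}

#' Emulate the immunobead secretion assay
#'
#' Generates bead events whose GRN-B fluorescence is a blank plus a linear
#' response to the secreted-protein concentration in the media, together with
#' optional residual-cell contaminant events. Beads are large, high-granularity
#' particles: their side scatter and SSC/FSC ratio separate them from the
#' carried-over cells, which is what the bead gates exploit.
#'
#' @param media_concentration Secreted protein level in the media (RPU-scale,
#'   `>= 0`).
#' @param config A [sim_config()] (`sec_slope`, noise settings).
#' @param n_contaminants Number of residual cell events to add (default 5%
#'   of the bead events).
#' @param time_h,reactor_id Metadata stamps.
#' @param seed Integer seed.
#' @return A raw `EventTable` data.frame (same schema as cell events).
#' @export
emulate_bead_assay <- function(media_concentration, config,
                               n_contaminants = NULL, time_h = 24,
                               reactor_id = "R1", seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(media_concentration) || length(media_concentration) != 1L ||
      !is.finite(media_concentration) || media_concentration < 0)
    stop("'media_concentration' must be a single non-negative number")
  cc <- cyto_constants()
  n <- cc$bead_n_events
  if (is.null(n_contaminants)) n_contaminants <- round(0.05 * n)
  with_seed(seed, {
    fsc <- stats::rlnorm(n, log(cc$bead_fsc_median), cc$bead_fsc_sdlog)
    ssc <- fsc * cc$bead_ssc_ratio * stats::rlnorm(n, 0, 0.15)
    grn <- (cc$bead_blank + config$sec_slope * media_concentration) *
      lognormal_noise(n, max(config$noise_cv, 0.02))
    beads <- data.frame(time_h = time_h, reactor_id = reactor_id,
                        FSC = fsc, SSC = ssc, GRN_B = grn,
                        BLU_V = cc$autofluor[["BLU_V"]] *
                          stats::rlnorm(n, 0, cc$autofluor_sdlog),
                        ORG_G = cc$autofluor[["ORG_G"]] *
                          stats::rlnorm(n, 0, cc$autofluor_sdlog))
    if (n_contaminants > 0) {
      m <- n_contaminants
      cells <- data.frame(time_h = time_h, reactor_id = reactor_id,
                          FSC = stats::rlnorm(m, log(cc$fsc_ref), cc$fsc_sdlog),
                          SSC = stats::rlnorm(m, log(cc$ssc_median), cc$ssc_sdlog),
                          GRN_B = cc$autofluor[["GRN_B"]] *
                            stats::rlnorm(m, 0, cc$autofluor_sdlog),
                          BLU_V = cc$autofluor[["BLU_V"]] *
                            stats::rlnorm(m, 0, cc$autofluor_sdlog),
                          ORG_G = cc$autofluor[["ORG_G"]] *
                            stats::rlnorm(m, 0, cc$autofluor_sdlog))
      beads <- rbind(beads, cells)
    }
    beads[sample.int(nrow(beads)), , drop = FALSE]
  })
}

#' Emulate a full sampled experiment: reactor run plus cytometry acquisition
#'
#' Convenience wrapper: runs [simulate_population()] and converts every
#' snapshot into a raw cytometry event table, concatenated in time order.
#'
#' @inheritParams simulate_population
#' @param reactor_id Reactor label.
#' @return List with `events` (one raw EventTable for the whole run),
#'   `reactor` (bioreactor series), `snapshots` and `times` as in
#'   [simulate_population()].
#' @export
simulate_experiment <- function(config, profile, duration_h,
                                reactor_id = "R1") {
  sim <- simulate_population(config, profile, duration_h)
  tabs <- lapply(seq_along(sim$times), function(i)
    emulate_cytometry(sim$snapshots[[i]], config, time_h = sim$times[i],
                      reactor_id = reactor_id,
                      seed = config$seed + 1000L + i))
  sim$events <- do.call(rbind, tabs)
  rownames(sim$events) <- NULL
  sim
}
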