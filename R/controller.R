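#' @title Real-time stress feedback control of induction
#' @description
#' The control law holds the population's mean UPR level at a reference: at
#' every cytometry sample (45-min period, matching the light-encoding
#' period), the light duty cycle is increased by a fixed step when the mean
#' UPR is below the reference and decreased by the same step when it is at
#' or above it. The default step is 5% of the sampling period (2 min 15 s of
#' light). Control starts from darkness (duty 0).
#' @name controller
NULL

#' Controller state
#'
#' @param threshold_rpu Reference mean-UPR level (RPU).
#' @param step Duty increment per sample (default 0.05 = 5% of the period).
#' @param sampling_min Sampling and light-encoding period (default 45 min).
#' @param duty Initial duty (default 0: start with no light).
#' @return List of class `"control_state"` with an empty actuation history.
#' @export
control_state <- function(threshold_rpu, step = 0.05, sampling_min = 45,
                          duty = 0) {
  stopifnot(is.numeric(threshold_rpu), length(threshold_rpu) == 1L,
            is.finite(threshold_rpu))
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive")
  if (duty < 0 || duty > 1) stop("'duty' must be in [0, 1]")
  structure(list(duty = duty, threshold_rpu = threshold_rpu, step = step,
                 sampling_min = sampling_min,
                 history = data.frame(time_h = numeric(0),
                                      mean_upr = numeric(0),
                                      duty = numeric(0))),
            class = "control_state")
}

#' @export
print.control_state <- function(x, ...) {
  cat("Stress feedback controller: duty", format(x$duty),
      "| reference", format(x$threshold_rpu), "RPU | step", x$step, "\n")
  cat("  actuation:", format(actuation_minutes(x), digits = 4), "min light per",
      x$sampling_min, "min period;", nrow(x$history), "samples seen\n")
  invisible(x)
}

#' One controller update
#'
#' Increases the duty by one step if the measured mean UPR is below the
#' reference, decreases it otherwise (a measurement exactly at the reference
#' counts as above: conservative on stress). The duty is clipped to `[0, 1]`.
#' A missing measurement (`NA`) holds the current duty and is logged.
#'
#' @param state A [control_state()].
#' @param mean_upr Measured population mean UPR (RPU), or `NA`.
#' @param time_h Optional time stamp for the history.
#' @return Updated `control_state`.
#' @export
control_step <- function(state, mean_upr, time_h = NA_real_) {
  stopifnot(inherits(state, "control_state"))
  if (length(mean_upr) != 1L)
    stop("'mean_upr' must be a single value")
  if (is.na(mean_upr)) {
    warning("missing UPR measurement; holding duty at ", state$duty)
  } else if (!is.finite(mean_upr)) {
    stop("'mean_upr' must be finite or NA")
  } else {
    delta <- if (mean_upr < state$threshold_rpu) state$step else -state$step
    state$duty <- min(1, max(0, state$duty + delta))
  }
  state$history <- rbind(state$history,
                         data.frame(time_h = time_h, mean_upr = mean_upr,
                                    duty = state$duty))
  state
}

#' Light-on minutes per period implied by the current duty
#'
#' @param state A [control_state()].
#' @return `duty * sampling_min`; one default step corresponds to 2.25 min
#'   (2 min 15 s) of a 45-min period.
#' @export
actuation_minutes <- function(state) {
  stopifnot(inherits(state, "control_state"))
  state$duty * state$sampling_min
}

#' Run a closed control loop against a plant
#'
#' The plant is a callable contract: `plant(duty)` applies `duty` for one
#' sampling period and returns the next sample's summary (a list or one-row
#' data.frame with at least `mean_upr_rpu`). Simulator-backed plants (see
#' [simulator_plant()]) also report the media secretion level. The loop
#' starts with no light, reads the mean UPR each period, and applies
#' [control_step()].
#'
#' @param plant Callable or [simulator_plant()] object.
#' @param threshold_rpu Reference mean-UPR level.
#' @param duration_h Control horizon in hours (at least 5 sampling periods).
#' @param step,sampling_min Controller settings (defaults 0.05 and 45).
#' @return List of class `"closed_loop_run"`: `history` (data.frame `time_h`,
#'   `duty`, `mean_upr`), `state` (final `control_state`), and, for
#'   simulator-backed plants, `endpoint_secretion` and `upr_samples`.
#' @export
run_closed_loop <- function(plant, threshold_rpu, duration_h,
                            step = 0.05, sampling_min = 45) {
  step_fn <- if (inherits(plant, "sim_plant")) plant$step else plant
  if (!is.function(step_fn)) stop("'plant' must be callable")
  period_h <- sampling_min / 60
  n_steps <- floor(duration_h / period_h + 1e-9)
  if (n_steps < 5L) stop("'duration_h' must cover at least 5 sampling periods")
  state <- control_state(threshold_rpu, step = step,
                         sampling_min = sampling_min, duty = 0)
  rows <- vector("list", n_steps)
  for (i in seq_len(n_steps)) {
    duty_cmd <- state$duty
    meas <- tryCatch(step_fn(duty_cmd), error = function(e)
      stop("plant failure at step ", i, ": ", conditionMessage(e)))
    meas <- as.list(meas)
    upr <- if (!is.null(meas$mean_upr_rpu)) meas$mean_upr_rpu else meas$mean_upr
    t_i <- i * period_h
    rows[[i]] <- data.frame(time_h = t_i, duty = duty_cmd,
                            mean_upr = if (is.null(upr)) NA_real_ else upr)
    state <- control_step(state, if (is.null(upr)) NA_real_ else upr,
                          time_h = t_i)
  }
  out <- list(history = do.call(rbind, rows), state = state)
  if (inherits(plant, "sim_plant")) {
    out$endpoint_secretion <- plant$secretion()
    out$upr_samples <- plant$upr_samples()
  }
  class(out) <- "closed_loop_run"
  out
}

#' @export
print.closed_loop_run <- function(x, ...) {
  h <- x$history
  cat("Closed-loop run:", nrow(h), "samples; final duty",
      format(h$duty[nrow(h)]), "\n")
  if (!is.null(x$endpoint_secretion))
    cat("  endpoint secretion:", format(x$endpoint_secretion, digits = 4), "\n")
  invisible(x)
}

#' Simulator-backed control plant
#'
#' Wraps the agent-based simulator as a plant for [run_closed_loop()]. The
#' reactor first runs `dark_h` hours in darkness (the controller's baseline
#' phase); each subsequent `plant$step(duty)` call applies the duty for one
#' sampling period, acquires a cytometry sample, processes it (gate, RPU,
#' strain split, baseline subtraction against the dark phase), and returns
#' the sample summary. Mirroring the wet-lab control experiments, the
#' accessory strain is omitted by default.
#'
#' @param config A [sim_config()]; `accessory_ratio = 0` by default here.
#' @param dark_h Dark baseline phase before control (default 3 h).
#' @param scale_factor Protein scale factor for the bead readout.
#' @return List of class `"sim_plant"` with functions `step(duty)`,
#'   `secretion()` (bead-assay level of the current media, against a blank),
#'   `upr_samples()` (per-sample interest-strain UPR value lists), and
#'   `time()` (current simulated hours since induction start).
#' @export
simulator_plant <- function(config, dark_h = 3, scale_factor = 1) {
  stopifnot(inherits(config, "sim_config"))
  config$accessory_ratio <- 0
  period_h <- config$sampling_min / 60
  env <- new.env(parent = emptyenv())
  env$state <- sim_init(config)
  env$sample_i <- 0L
  env$upr_samples <- list()

  acquire <- function() {
    env$sample_i <- env$sample_i + 1L
    emulate_cytometry(sim_snapshot(env$state), config,
                      time_h = env$state$t, reactor_id = "plant",
                      seed = config$seed + 5000L + env$sample_i)
  }
  # dark baseline phase: sample every period, pool the last 2 h for baseline
  dark_tabs <- list()
  n_dark <- max(1L, floor(dark_h / period_h + 1e-9))
  for (i in seq_len(n_dark)) {
    env$state <- sim_advance(env$state, config, 0, i * period_h)
    dark_tabs[[i]] <- acquire()
  }
  dark_raw <- do.call(rbind, dark_tabs)
  refs <- default_rpu_references()
  dark_rpu <- to_rpu(gate_cells(dark_raw), refs)
  dark_int <- split_strains(dark_rpu)$interest
  win <- dark_int$time_h >= env$state$t - 2
  env$baseline <- vapply(FLUOR_CHANNELS,
                         function(ch) mean(dark_int[[ch]][win]), numeric(1L))
  env$t0 <- env$state$t

  process_one <- function(tab) {
    rpu <- to_rpu(gate_cells(tab), refs)
    parts <- split_strains(rpu)
    interest <- subtract_baseline(parts$interest, env$baseline)
    env$upr_samples[[length(env$upr_samples) + 1L]] <- interest$ORG_G
    summarize_sample(interest, parts$accessory,
                     n_unclassified = nrow(parts$unclassified),
                     n_events_total = nrow(tab))
  }

  structure(list(
    step = function(duty) {
      stopifnot(is.numeric(duty), duty >= 0, duty <= 1)
      env$state <- sim_advance(env$state, config, duty,
                               env$state$t + period_h)
      process_one(acquire())
    },
    secretion = function() {
      beads <- gate_beads(emulate_bead_assay(
        env$state$media_sec, config, seed = config$seed + 9001L))
      blank <- gate_beads(emulate_bead_assay(
        0, config, seed = config$seed + 9002L))
      quantify_secretion(beads, blank, fraction_interest = 1,
                         scale_factor = scale_factor)$secretion_level
    },
    upr_samples = function() env$upr_samples,
    time = function() env$state$t - env$t0
  ), class = "sim_plant")
}

#' Compare feedback and constant-induction strategies
#'
#' Runs closed-loop control at each reference stress level and constant
#' induction at each given duty, on identically-seeded plants, and tabulates
#' for each strategy the mean UPR over the last 8 h, the endpoint secretion
#' level, and the maximal UPR-accumulator fraction (classifier threshold
#' from each run's own final sample).
#'
#' @param plant_factory Zero-argument function returning a fresh
#'   [simulator_plant()] (identical seeding across calls).
#' @param thresholds Reference mean-UPR levels for closed-loop runs.
#' @param constant_duties Constant duty levels for open-loop runs.
#' @param duration_h Horizon per run (default 24).
#' @param step,sampling_min Controller settings.
#' @return Data.frame: `strategy`, `setting`, `mean_upr_last_8h`,
#'   `endpoint_secretion`, `max_upr_accumulator_fraction`.
#' @export
compare_strategies <- function(plant_factory, thresholds, constant_duties,
                               duration_h = 24, step = 0.05,
                               sampling_min = 45) {
  if (length(thresholds) == 0L && length(constant_duties) == 0L)
    stop("no strategies given")
  period_h <- sampling_min / 60
  n_last <- max(1L, round(8 / period_h))  # samples in the final 8 h

  eval_run <- function(upr_means, upr_samples, secretion) {
    m <- length(upr_means)
    last <- upr_means[max(1L, m - n_last + 1L):m]
    final <- upr_samples[[m]]
    maxfrac <- tryCatch({
      thr <- accumulator_threshold(final[is.finite(final)])
      max(vapply(upr_samples, function(x) mean(x > thr), numeric(1L)))
    }, error = function(e) NA_real_, warning = function(w) {
      thr <- suppressWarnings(accumulator_threshold(final[is.finite(final)]))
      max(vapply(upr_samples, function(x) mean(x > thr), numeric(1L)))
    })
    c(mean_upr_last_8h = mean(last), endpoint_secretion = secretion,
      max_upr_accumulator_fraction = maxfrac)
  }

  rows <- list()
  for (th in thresholds) {
    run <- run_closed_loop(plant_factory(), th, duration_h, step = step,
                           sampling_min = sampling_min)
    met <- eval_run(run$history$mean_upr, run$upr_samples,
                    run$endpoint_secretion)
    rows[[length(rows) + 1L]] <-
      data.frame(strategy = "closed_loop", setting = th, t(met))
  }
  for (dd in constant_duties) {
    plant <- plant_factory()
    n_steps <- floor(duration_h / period_h + 1e-9)
    upr <- numeric(n_steps)
    for (i in seq_len(n_steps)) upr[i] <- plant$step(dd)$mean_upr_rpu
    met <- eval_run(upr, plant$upr_samples(), plant$secretion())
    rows[[length(rows) + 1L]] <-
      data.frame(strategy = "constant", setting = dd, t(met))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
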