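#' @title End-to-end characterization and control campaigns
#' @description
#' Orchestration of the full analysis on synthetic experiments: simulate a
#' reactor per induction level, process the raw events, detect accumulators,
#' quantify secretion, and fit the secretion model per induction
#' ([run_characterization()]); or run closed-loop and constant-induction
#' strategies side by side ([run_control_campaign()]). All runs are
#' deterministic under the configured seed.
#' @name cli_pipeline
NULL

#' Campaign configuration
#'
#' @param scenario Simulator scenario preset (see [scenario_config()]).
#' @param induction_grid Duty levels for characterization reactors.
#' @param thresholds Reference stress levels for control campaigns.
#' @param constant_duties Constant-duty comparators for control campaigns.
#' @param dark_h Dark (baseline) phase before induction (default 3 h).
#' @param duration_h Induced phase duration (default 24 h).
#' @param seed Master seed; reactor `i` uses `seed + i`.
#' @param scale_factor Protein-specific bead scale factor.
#' @param coeffs Channel-correction coefficients.
#' @param ... Simulator overrides passed to [scenario_config()].
#' @return List of class `"experiment_config"`.
#' @export
experiment_config <- function(scenario = "scfv",
                              induction_grid = seq(0, 1, by = 0.2),
                              thresholds = numeric(0),
                              constant_duties = numeric(0),
                              dark_h = 3, duration_h = 24,
                              seed = 1L, scale_factor = 1,
                              coeffs = c(GRN_B = 1, BLU_V = 1, ORG_G = 1),
                              ...) {
  if (any(induction_grid < 0 | induction_grid > 1))
    stop("'induction_grid' duties must be in [0, 1]")
  if (dark_h < 2) stop("'dark_h' must leave a 2-h baseline window")
  structure(list(scenario = scenario, induction_grid = induction_grid,
                 thresholds = thresholds, constant_duties = constant_duties,
                 dark_h = dark_h, duration_h = duration_h,
                 seed = as.integer(seed), scale_factor = scale_factor,
                 coeffs = coeffs, sim_overrides = list(...)),
            class = "experiment_config")
}

#' Accumulator analysis of one processed run
#'
#' Computes, for the iPOI (GRN-B) and UPR (ORG-G) channels of the
#' strain-of-interest events: the classifier threshold from the final
#' (steady-state) sample, the accumulator fraction series, and the
#' non-accumulator median iPOI series (via the Gaussian-mixture split) used
#' for model fitting.
#'
#' @param interest Baseline-subtracted strain-of-interest `EventTable`.
#' @param induction_start_h Induction start (threshold sample is the last
#'   one; series times are reported relative to induction start).
#' @return List with `ipoi` and `upr` ([accumulator_fraction_series()]
#'   results), and `non_accumulator_series` (data.frame `time_h`, `value`).
#' @export
analyze_run <- function(interest, induction_start_h) {
  times <- sort(unique(interest$time_h))
  by_time <- function(ch) lapply(times, function(tt)
    interest[[ch]][interest$time_h == tt])
  ipoi_samples <- by_time("GRN_B")
  upr_samples <- by_time("ORG_G")
  final_i <- ipoi_samples[[length(times)]]
  final_u <- upr_samples[[length(times)]]
  rel_t <- times - induction_start_h

  acc_or_na <- function(final, samples, channel) {
    tryCatch({
      thr <- accumulator_threshold(final)
      accumulator_fraction_series(samples, rel_t, thr, channel = channel)
    }, error = function(e) NULL)
  }
  ipoi <- acc_or_na(final_i, ipoi_samples, "iPOI")
  upr <- acc_or_na(final_u, upr_samples, "UPR")

  non_acc <- do.call(rbind, lapply(seq_along(times), function(i) {
    x <- ipoi_samples[[i]]
    med <- tryCatch({
      sp <- split_subpopulations_gmm(x)
      stats::median(sp$non_accumulator)
    }, error = function(e) stats::median(x[is.finite(x)]))
    data.frame(time_h = rel_t[i], value = med)
  }))
  list(ipoi = ipoi, upr = upr, non_accumulator_series = non_acc)
}

#' Characterization campaign: one reactor per induction level
#'
#' For every induction level: simulate the reactor and its cytometry
#' acquisition, process the events, analyze accumulators, measure secretion
#' with the bead assay (blank-subtracted against a zero-concentration bead
#' sample, normalized by the measured fraction of interest cells), and fit
#' the secretion model's trafficking parameters on the non-accumulator
#' series plus the secretion endpoint.
#'
#' @param config An [experiment_config()].
#' @param fit Logical: run the per-induction model fits (default TRUE; the
#'   CMA-ES fits dominate the runtime).
#' @param fixed_params Calibrated `Kprd`, `Kdil`, `Kunits` for the fits.
#'   Defaults: the package's physiological rates and, for `Kunits`, the
#'   emulated bead assay's fluorescence slope (internal RPU to bead units);
#'   replace with [calibrate_units()] output when the assay scale differs.
#' @return List of class `"characterization"` with one element per reactor
#'   (`summaries`, `accumulators`, `secretion`, `fit`, `induction_rpu`,
#'   `reactor`), plus `dose_response` (per-induction table) and `fits`
#'   (parameter trend table if fitted).
#' @export
run_characterization <- function(config, fit = TRUE,
                                 fixed_params = list(Kprd = 60 * log(2) / 20,
                                                     Kdil = 60 * log(2) / 90,
                                                     Kunits = 120)) {
  stopifnot(inherits(config, "experiment_config"))
  total_h <- config$dark_h + config$duration_h
  reactors <- vector("list", length(config$induction_grid))
  for (i in seq_along(config$induction_grid)) {
    ind <- config$induction_grid[i]
    sim_cfg <- do.call(scenario_config,
                       c(list(scenario = config$scenario,
                              seed = config$seed + i),
                         config$sim_overrides))
    prof <- induction_profile(c(0, config$dark_h), c(0, ind))
    sim <- simulate_experiment(sim_cfg, prof, total_h,
                               reactor_id = paste0("R", i))
    proc <- process_events(sim$events, coeffs = config$coeffs,
                           induction_start_h = config$dark_h)
    ana <- analyze_run(proc$interest, config$dark_h)

    # bead assay on the final media concentration, blanked at zero
    beads <- gate_beads(emulate_bead_assay(
      sim$reactor$media_sec[nrow(sim$reactor)], sim_cfg,
      seed = sim_cfg$seed + 7001L, reactor_id = paste0("R", i)))
    blank <- gate_beads(emulate_bead_assay(
      0, sim_cfg, seed = sim_cfg$seed + 7002L))
    frac_int <- proc$summaries$fraction_interest[nrow(proc$summaries)]
    secretion <- quantify_secretion(beads, blank, frac_int,
                                    config$scale_factor)

    # measured normalized induction: accessory red level over the last 4
    # samples; the campaign-wide maximum normalizes to [0, 1] below
    last_t <- utils::tail(sort(unique(proc$accessory$time_h)), 4)
    ind_rpu_raw <- mean(proc$accessory$ORG_G[proc$accessory$time_h %in% last_t])

    reactors[[i]] <- list(induction_duty = ind,
                          summaries = proc$summaries,
                          accumulators = ana,
                          secretion = secretion,
                          induction_rpu_raw = ind_rpu_raw,
                          non_accumulator_series = ana$non_accumulator_series,
                          reactor = sim$reactor)
  }

  global_max <- max(vapply(reactors, function(r) r$induction_rpu_raw,
                           numeric(1L)), na.rm = TRUE)
  for (i in seq_along(reactors))
    reactors[[i]]$induction_measured <-
      induction_level(reactors[[i]]$induction_rpu_raw, global_max)

  dose <- do.call(rbind, lapply(reactors, function(r) {
    data.frame(
      induction_duty = r$induction_duty,
      induction_measured = r$induction_measured,
      max_fraction_ipoi = if (!is.null(r$accumulators$ipoi))
        r$accumulators$ipoi$max_fraction else NA_real_,
      max_time_ipoi_h = if (!is.null(r$accumulators$ipoi))
        r$accumulators$ipoi$max_time_h else NA_real_,
      max_fraction_upr = if (!is.null(r$accumulators$upr))
        r$accumulators$upr$max_fraction else NA_real_,
      mean_upr_24h = r$summaries$mean_upr_rpu[nrow(r$summaries)],
      median_ipoi_24h = r$summaries$median_iPOI_rpu[nrow(r$summaries)],
      secretion_level = r$secretion$secretion_level)
  }))

  fits <- NULL
  if (fit) {
    fit_list <- list()
    for (i in seq_along(reactors)) {
      r <- reactors[[i]]
      ind_m <- r$induction_measured
      if (is.na(ind_m) || ind_m < 0.05) next
      series <- r$non_accumulator_series
      series <- series[series$time_h >= 0, ]
      f <- tryCatch(
        fit_per_induction(series, r$secretion$secretion_level,
                          fixed = fixed_params, induction = ind_m,
                          sec_time_h = max(series$time_h),
                          protein_id = config$scenario,
                          seed = config$seed + i),
        error = function(e) NULL)
      if (!is.null(f)) fit_list[[length(fit_list) + 1L]] <- f
    }
    if (length(fit_list)) fits <- parameter_trend(fit_list)
  }

  structure(list(reactors = reactors, dose_response = dose, fits = fits,
                 config = config),
            class = "characterization")
}

#' @export
print.characterization <- function(x, ...) {
  cat("Characterization campaign (", x$config$scenario, "), ",
      length(x$reactors), " reactors\n", sep = "")
  print(x$dose_response, row.names = FALSE, digits = 3)
  if (!is.null(x$fits)) {
    cat("\nFitted rates per induction:\n")
    print(x$fits, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Control campaign: feedback strategies versus constant induction
#'
#' Wraps [compare_strategies()] end to end from raw synthetic events, using
#' identically-seeded simulator plants for every strategy.
#'
#' @param config An [experiment_config()] with non-empty `thresholds` and/or
#'   `constant_duties`.
#' @return The strategy comparison table (see [compare_strategies()]).
#' @export
run_control_campaign <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (length(config$thresholds) == 0L && length(config$constant_duties) == 0L)
    stop("config lists no thresholds and no constant duties")
  factory <- function() {
    sim_cfg <- do.call(scenario_config,
                       c(list(scenario = config$scenario, seed = config$seed),
                         config$sim_overrides))
    simulator_plant(sim_cfg, dark_h = config$dark_h,
                    scale_factor = config$scale_factor)
  }
  compare_strategies(factory, config$thresholds, config$constant_duties,
                     duration_h = config$duration_h)
}
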