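#' @title Staged calibration of the secretion model
#' @description
#' Calibration proceeds in three stages, each of which pins down part of the
#' parameter vector so that the per-protein, per-induction fits only have to
#' estimate the three trafficking-related rates:
#' \enumerate{
#'   \item [fit_reporter_stage()] fits `Kprd` and `Kdil` on a strain expressing
#'     a non-secreted reporter (`Ksec = Kdeg = 0`), with `Ktrf` as a nuisance
#'     scale.
#'   \item [calibrate_units()] sets the internal-to-secreted scale `Kunits`
#'     from a secreted-reporter measurement.
#'   \item [fit_per_induction()] fits `Ktrf`, `Ksec`, `Kdeg` independently for
#'     each induction level on the non-accumulator subpopulation time series
#'     plus the 24-h secretion endpoint.
#' }
#' All optimization runs CMA-ES in log-parameter space, which enforces
#' positivity of the rates without explicit constraints.
#' @name secretion_fitting
NULL

new_secretion_fit <- function(params, objective, induction, protein_id,
                              converged, stage, free, history, seed,
                              details = list()) {
  structure(
    c(list(params = params, objective = objective, induction = induction,
           protein_id = protein_id, converged = converged, stage = stage,
           free = free, history = history, seed = seed), details),
    class = "secretion_fit"
  )
}

#' @export
print.secretion_fit <- function(x, ...) {
  cat("Secretion model fit (stage: ", x$stage, ")\n", sep = "")
  if (!is.null(x$protein_id)) cat("  protein:  ", x$protein_id, "\n", sep = "")
  cat("  induction:", format(x$induction), "\n")
  cat("  objective:", format(x$objective), " converged:", x$converged, "\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  print(unlist(unclass(x$params)))
  invisible(x)
}

#' @export
coef.secretion_fit <- function(object, ...) unlist(unclass(object$params))

#' Model trajectory implied by a fit
#'
#' @param object A `secretion_fit`.
#' @param times Time grid in hours; defaults to the fitted series' grid.
#' @param ... Unused.
#' @return Trajectory data.frame from [simulate_ode()] at the fit's induction.
#' @export
predict.secretion_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) times <- object$data$time_h
  simulate_ode(object$params, constant_induction(object$induction, from = 0),
               times)
}

#' @export
residuals.secretion_fit <- function(object, ...) {
  pred <- predict(object)
  object$data$value - pred$Trf[match(object$data$time_h, pred$time_h)]
}

trf_on_grid <- function(params, induction, times) {
  t0 <- min(0, times[1L])
  grid <- sort(unique(c(t0, times)))
  traj <- simulate_ode(params, constant_induction(induction, from = t0), grid)
  traj$Trf[match(times, traj$time_h)]
}

check_series <- function(series) {
  if (!is.data.frame(series) || !all(c("time_h", "value") %in% names(series)))
    stop("series must be a data.frame with columns 'time_h' and 'value'")
  series <- series[order(series$time_h), c("time_h", "value")]
  if (any(!is.finite(series$time_h)) || any(!is.finite(series$value)))
    stop("series contains non-finite entries")
  series
}

#' First-stage fit: production and dilution rates from a non-secreted reporter
#'
#' Fits the model with `Ksec = Kdeg = 0` to the internal fluorescence time
#' series of a strain expressing a non-secreted reporter, by least squares on
#' `Trf(t)`. `Kprd` and `Kdil` are the estimands; `Ktrf` is a free nuisance
#' scale. With `Ktrf` free, the likelihood is invariant under exchanging
#' `Kprd` and `Kdil` (the rise curve is symmetric in the two rates up to a
#' rescaling of `Ktrf`), so the fit adopts the physiological labelling
#' `Kprd >= Kdil`: the production intermediate (mRNA-like, half-life tens of
#' minutes) turns over faster than the culture dilutes (generation time above
#' an hour).
#'
#' @param series Data.frame with columns `time_h`, `value` (internal reporter
#'   level, RPU, baseline-subtracted, starting at induction onset). Needs at
#'   least 8 samples spanning at least 6 h of the pre-steady-state rise.
#' @param induction Constant induction duty in `(0, 1]` applied from `t = 0`.
#' @param residual_scale `"log"` (default) or `"linear"` residuals. Cytometry
#'   measurement noise is multiplicative, so log residuals are the matched
#'   likelihood; they weight the early rise - the only part of the series
#'   informative about the fast intermediate turnover - on equal footing with
#'   the plateau.
#' @param seed Integer seed for the optimizer.
#' @param max_iter CMA-ES generation budget.
#' @return A `secretion_fit`; `coef()` includes fitted `Kprd`, `Kdil`, `Ktrf`.
#' @export
fit_reporter_stage <- function(series, induction, residual_scale = c("log", "linear"),
                               seed = 1L, max_iter = 200) {
  residual_scale <- match.arg(residual_scale)
  series <- check_series(series)
  if (nrow(series) < 8L || diff(range(series$time_h)) < 6)
    stop("reporter series must have >= 8 samples spanning >= 6 h")
  if (!is.numeric(induction) || induction <= 0 || induction > 1)
    stop("'induction' must be in (0, 1]")
  if (stats::sd(series$value) == 0 || max(abs(series$value)) == 0)
    stop("reporter series is flat: Kprd and Kdil are non-identifiable")

  obs <- series$value
  times <- series$time_h
  # heuristic start: generation-time-scale dilution, fast intermediate,
  # Ktrf from the steady-state plateau
  kdil0 <- 0.5
  kprd0 <- 2
  ktrf0 <- max(obs) * kdil0 / induction
  if (!is.finite(ktrf0) || ktrf0 <= 0) ktrf0 <- 1

  objective <- function(x) {
    k <- exp(x)
    p <- model_params(Kprd = k[1L], Ktrf = k[3L], Ksec = 0, Kdeg = 0,
                      Kdil = k[2L])
    pred <- tryCatch(trf_on_grid(p, induction, times), error = function(e) NULL)
    if (is.null(pred)) return(Inf)
    if (residual_scale == "log") {
      ok <- pred > 0 & obs > 0
      if (sum(ok) < 4L) return(Inf)
      sum((log(pred[ok]) - log(obs[ok]))^2)
    } else {
      sum((pred - obs)^2)
    }
  }

  res <- cma_es(objective, log(c(kprd0, kdil0, ktrf0)), sigma0 = 0.7,
                max_iter = max_iter, seed = seed)
  k <- exp(res$par)
  if (k[1L] < k[2L]) {  # swap-degeneracy convention: Kprd >= Kdil
    k <- c(k[2L], k[1L], k[3L] * k[1L] / k[2L])
  }
  params <- model_params(Kprd = k[1L], Ktrf = k[3L], Ksec = 0, Kdeg = 0,
                         Kdil = k[2L])
  new_secretion_fit(params, res$value, induction, protein_id = "reporter",
                    converged = res$converged, stage = "reporter",
                    free = c("Kprd", "Kdil", "Ktrf"), history = res$history,
                    seed = seed, details = list(data = series,
                                                residual_scale = residual_scale))
}

#' Generation time and intermediate half-life implied by a reporter fit
#'
#' Converts the fitted dilution rate to a cell generation time and the fitted
#' intermediate turnover rate to a half-life, both in minutes
#' (`t_half = ln 2 / K`).
#'
#' @param fit A `secretion_fit` from [fit_reporter_stage()].
#' @return Named vector `c(generation_time_min, prd_halflife_min)`.
#' @export
reporter_timescales <- function(fit) {
  stopifnot(inherits(fit, "secretion_fit"), fit$stage == "reporter")
  c(generation_time_min = 60 * log(2) / fit$params$Kdil,
    prd_halflife_min = 60 * log(2) / fit$params$Kprd)
}

#' Second-stage calibration of the internal-to-secreted scale
#'
#' `Kunits` converts internal fluorescence (RPU) into the secreted-protein
#' scale of the bead assay. Because the secreted pool is linear in `Kunits`,
#' the calibration is a one-line ratio: simulate the model at `Kunits = 1`
#' and scale so that `Sec(t_end)` matches the measured secretion level of the
#' secreted-reporter strain.
#'
#' @param sec_level Measured secretion level at `t_end` (positive).
#' @param params [model_params()] with provisional `Ktrf`, `Ksec`, `Kdeg`
#'   from a joint fit of the secreted-reporter strain (`Ksec > 0`).
#' @param induction Constant induction duty of the calibration experiment.
#' @param t_end Measurement time in hours (default 24).
#' @return Fitted `Kunits` (scalar).
#' @export
calibrate_units <- function(sec_level, params, induction, t_end = 24) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(sec_level) || length(sec_level) != 1L || sec_level <= 0)
    stop("'sec_level' must be a single positive secretion measurement")
  if (params$Ksec <= 0)
    stop("'params' must carry a provisional positive Ksec")
  p1 <- model_params(Kprd = params$Kprd, Ktrf = params$Ktrf, Ksec = params$Ksec,
                     Kdeg = params$Kdeg, Kdil = params$Kdil, Kunits = 1)
  traj <- simulate_ode(p1, constant_induction(induction, from = 0),
                       sort(unique(c(0, t_end / 2, t_end))))
  sec1 <- traj$Sec[traj$time_h == t_end]
  if (sec1 <= 0) stop("model secretes nothing at t_end; cannot calibrate Kunits")
  sec_level / sec1
}

#' Third-stage fit: trafficking, secretion and degradation rates
#'
#' Fits `Ktrf`, `Ksec`, `Kdeg` for one protein at one induction level, with
#' `Kprd`, `Kdil`, `Kunits` held at their calibrated values. The data are the
#' internal-protein time series of the non-accumulator subpopulation (see
#' [split_subpopulations_gmm()]) and the secretion endpoint at `sec_time_h`.
#' The objective is a weighted least squares,
#' `J = sum_t (Trf_model - Trf_obs)^2 / sigma_trf^2
#'     + w (Sec_model - sec_endpoint)^2 / sigma_sec^2`,
#' with `sigma_trf` the series' median absolute deviation, `sigma_sec` 10% of
#' the endpoint, and `w` the number of time points, so the single endpoint
#' carries weight comparable to the whole series.
#'
#' @param trf_series Data.frame `time_h`, `value`: non-accumulator internal
#'   protein levels (RPU), at least 10 points.
#' @param sec_endpoint Secretion level at `sec_time_h`, or `NA` to fit the
#'   time series only (then `Ksec` and `Kdeg` are flagged non-identifiable:
#'   only their sum is constrained).
#' @param fixed Named list or vector with `Kprd`, `Kdil`, `Kunits`.
#' @param induction Constant induction duty of the experiment.
#' @param sec_time_h Endpoint time (default 24).
#' @param protein_id Label carried into the result.
#' @param residual_scale `"linear"` (default) or `"log"` series residuals.
#' @param seed,max_iter Optimizer controls.
#' @return A `secretion_fit` with fitted `Ktrf`, `Ksec`, `Kdeg`.
#' @export
fit_per_induction <- function(trf_series, sec_endpoint, fixed, induction,
                              sec_time_h = 24, protein_id = "POI",
                              residual_scale = c("linear", "log"),
                              seed = 1L, max_iter = 200) {
  residual_scale <- match.arg(residual_scale)
  series <- check_series(trf_series)
  if (nrow(series) < 10L) stop("need at least 10 time points")
  fixed <- as.list(fixed)
  if (!all(c("Kprd", "Kdil", "Kunits") %in% names(fixed)))
    stop("'fixed' must provide Kprd, Kdil and Kunits")
  if (!is.numeric(induction) || induction <= 0 || induction > 1)
    stop("'induction' must be in (0, 1]")
  have_endpoint <- !is.null(sec_endpoint) && length(sec_endpoint) == 1L &&
    is.finite(sec_endpoint)
  if (!have_endpoint)
    warning("no secretion endpoint: Ksec and Kdeg are non-identifiable ",
            "(only their sum is constrained)")

  obs <- series$value
  times <- series$time_h
  # robust residual scale: MAD of a mostly-plateaued series estimates the
  # measurement noise; floored at 1% of the signal amplitude so that
  # noise-free synthetic data do not degenerate the weighting
  sigma_trf <- max(stats::mad(obs), 0.01 * max(abs(obs)), 1e-9)
  sigma_sec <- 0.1 * max(abs(if (have_endpoint) sec_endpoint else 0),
                         0.1 * max(abs(obs)) * fixed$Kunits)
  w_sec <- nrow(series)

  # search space: log total outflux and logit secreted share instead of
  # (log Ksec, log Kdeg) — the series constrains Ksec + Kdeg and the endpoint
  # constrains the split, so this parametrization decouples the two terms
  dt <- diff(times); dv <- diff(obs)
  slope <- suppressWarnings(max(dv / dt, na.rm = TRUE))
  ktrf0 <- max(slope / induction, 0.1)
  x0 <- c(log(ktrf0), log(0.2), 0)

  sim_times <- sort(unique(c(times, sec_time_h)))
  objective <- function(x) {
    ktrf <- exp(x[1L]); kout <- exp(x[2L]); share <- stats::plogis(x[3L])
    if (!is.finite(ktrf) || !is.finite(kout)) return(Inf)
    p <- model_params(Kprd = fixed$Kprd, Ktrf = ktrf, Ksec = kout * share,
                      Kdeg = kout * (1 - share), Kdil = fixed$Kdil,
                      Kunits = fixed$Kunits)
    traj <- tryCatch(
      simulate_ode(p, constant_induction(induction, from = min(0, sim_times[1L])),
                   sort(unique(c(min(0, sim_times[1L]), sim_times)))),
      error = function(e) NULL)
    if (is.null(traj)) return(Inf)
    pred <- traj$Trf[match(times, traj$time_h)]
    J <- if (residual_scale == "log") {
      ok <- pred > 0 & obs > 0
      if (sum(ok) < 5L) return(Inf)
      sum((log(pred[ok]) - log(obs[ok]))^2) / stats::mad(log(obs[ok]), na.rm = TRUE)^2
    } else {
      sum((pred - obs)^2) / sigma_trf^2
    }
    if (have_endpoint) {
      sec_pred <- traj$Sec[match(sec_time_h, traj$time_h)]
      J <- J + w_sec * (sec_pred - sec_endpoint)^2 / sigma_sec^2
    }
    J
  }

  res <- cma_es(objective, x0, sigma0 = 0.7, max_iter = max_iter, seed = seed)
  ktrf <- exp(res$par[1L]); kout <- exp(res$par[2L])
  share <- stats::plogis(res$par[3L])
  params <- model_params(Kprd = fixed$Kprd, Ktrf = ktrf, Ksec = kout * share,
                         Kdeg = kout * (1 - share), Kdil = fixed$Kdil,
                         Kunits = fixed$Kunits)
  new_secretion_fit(params, res$value, induction, protein_id = protein_id,
                    converged = res$converged, stage = "per_induction",
                    free = c("Ktrf", "Ksec", "Kdeg"), history = res$history,
                    seed = seed,
                    details = list(data = series, sec_endpoint =
                                     if (have_endpoint) sec_endpoint else NA_real_,
                                   sec_time_h = sec_time_h,
                                   identifiable = have_endpoint,
                                   residual_scale = residual_scale))
}

#' Fitted-rate trends across induction levels
#'
#' Collects per-induction fits into a table sorted by induction, for
#' inspecting how the trafficking, secretion and degradation rates respond to
#' production demand — in particular whether `Kdeg` turns upward above the
#' accumulator-appearance threshold.
#'
#' @param fits List of `secretion_fit` objects from [fit_per_induction()].
#' @return Data.frame `induction`, `Ktrf`, `Ksec`, `Kdeg`, `objective`,
#'   `converged`, sorted by induction. Duplicate induction levels are kept
#'   with a warning.
#' @export
parameter_trend <- function(fits) {
  if (length(fits) == 0L) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, logical(1L), "secretion_fit")))
  tab <- do.call(rbind, lapply(fits, function(f)
    data.frame(induction = f$induction, Ktrf = f$params$Ktrf,
               Ksec = f$params$Ksec, Kdeg = f$params$Kdeg,
               objective = f$objective, converged = f$converged)))
  if (anyDuplicated(tab$induction))
    warning("duplicate induction levels present; keeping all rows")
  tab[order(tab$induction), , drop = FALSE]
}
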