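#' @title Accumulator detection and threshold statistics
#' @description
#' "Accumulators" are cells transiently trapped in secretion burnout: their
#' internal protein (or stress reporter) level sits far above the bulk of the
#' population. They are detected against the steady-state (24 h
#' post-induction) distribution, when the population is monomodal again: a
#' normal distribution is fitted to the log10 of the 24-h levels and the
#' classifier threshold is its mean plus three standard deviations. The
#' fraction of cells above the threshold, tracked through time, peaks a few
#' hours after induction; its maximum over the run ("maximal accumulator
#' fraction") is the dose metric used to find induction and stress
#' thresholds.
#' @name population_stats
NULL

#' Accumulator classifier threshold from the steady-state sample
#'
#' Fits a normal distribution to `log10` of the positive values (cytometry
#' distributions are approximately log-normal; a `domain = "linear"` switch
#' fits the raw values instead) and returns the level three standard
#' deviations above the mean, back-transformed. Warns if the sample looks
#' bimodal, since the classifier is only calibrated on a monomodal
#' steady-state distribution.
#'
#' @param values_24h RPU values of the strain of interest at 24 h
#'   post-induction (at least 500 events).
#' @param domain `"log10"` (default) or `"linear"`.
#' @return Threshold in RPU.
#' @export
accumulator_threshold <- function(values_24h, domain = c("log10", "linear")) {
  domain <- match.arg(domain)
  x <- values_24h[is.finite(values_24h)]
  if (length(x) < 500L)
    stop("need at least 500 events to fit the steady-state distribution")
  if (domain == "log10") {
    x <- x[x > 0]
    if (length(x) < 500L)
      stop("need at least 500 positive events for a log-domain fit")
    lx <- log10(x)
    mu <- mean(lx); sg <- stats::sd(lx)
    # same separation rule as the mixture split: < 0.3 decades is monomodal
    if (looks_bimodal(lx, min_sep = 0.3))
      warning("24-h distribution looks bimodal; mean+3sd threshold is only ",
              "calibrated on a monomodal steady state")
    10^(mu + 3 * sg)
  } else {
    mu <- mean(x); sg <- stats::sd(x)
    if (looks_bimodal(x))
      warning("24-h distribution looks bimodal; mean+3sd threshold is only ",
              "calibrated on a monomodal steady state")
    mu + 3 * sg
  }
}

# deterministic 2-component EM fit; initialized from quantile-spanning order
# statistics so the starting partition straddles any second mode
#' @importFrom mclust Mclust mclustBIC
gmm2_fit <- function(x) {
  n <- length(x)
  if (stats::sd(x) < .Machine$double.eps^0.5) return(NULL)
  sub <- order(x)[unique(round(seq(1, n, length.out = min(1000L, n))))]
  tryCatch(
    suppressWarnings(Mclust(x, G = 2, modelNames = "V",
                            initialization = list(subset = sub),
                            verbose = FALSE)),
    error = function(e) NULL)
}

# bimodality heuristic for the classifier precondition: a two-component
# mixture must beat a single normal decisively and be genuinely separated
looks_bimodal <- function(x, min_sep = 0) {
  n <- length(x)
  if (n < 500L || stats::sd(x) < .Machine$double.eps^0.5) return(FALSE)
  xs <- sort(x)
  sub <- xs[unique(round(seq(1, n, length.out = min(4000L, n))))]
  f2 <- gmm2_fit(sub)
  if (is.null(f2) || length(f2$parameters$mean) < 2L) return(FALSE)
  means <- f2$parameters$mean
  pro <- f2$parameters$pro
  sg <- sqrt(mean(f2$parameters$variance$sigmasq))
  if (abs(diff(means)) < max(2 * sg, min_sep)) return(FALSE)
  # only a distinct upper mode invalidates the steady-state classifier; a
  # small lower shoulder (baseline-subtraction artifact) does not
  pro_up <- pro[which.max(means)]
  if (pro_up < 0.02 || pro_up > 0.6) return(FALSE)
  f1 <- tryCatch(suppressWarnings(Mclust(sub, G = 1, verbose = FALSE)),
                 error = function(e) NULL)
  is.null(f1) || (f2$bic - f1$bic > 20)
}

#' Accumulator fraction through time
#'
#' Applies a fixed classifier threshold to every sample of a run and records
#' the fraction of events above it, its maximum and the time of the maximum.
#'
#' @param samples Named list: each element the RPU values of one sample.
#' @param times Sample times in hours (same length as `samples`).
#' @param threshold_rpu Classifier threshold (from [accumulator_threshold()]
#'   of the same run's 24-h sample).
#' @param channel Label: `"iPOI"` or `"UPR"`.
#' @return List of class `"accumulator_result"` with `threshold_rpu`,
#'   `fraction_series` (data.frame `time_h`, `fraction`), `max_fraction`,
#'   `max_time_h`, `channel`.
#' @export
accumulator_fraction_series <- function(samples, times, threshold_rpu,
                                        channel = c("iPOI", "UPR")) {
  channel <- match.arg(channel)
  stopifnot(length(samples) == length(times))
  frac <- vapply(samples, function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) return(NA_real_)
    mean(x > threshold_rpu)
  }, numeric(1L))
  series <- data.frame(time_h = as.numeric(times), fraction = frac)
  if (all(is.na(frac))) stop("all samples empty")
  imax <- which.max(frac)
  structure(list(threshold_rpu = threshold_rpu,
                 fraction_series = series,
                 max_fraction = frac[imax],
                 max_time_h = series$time_h[imax],
                 channel = channel),
            class = "accumulator_result")
}

#' @export
print.accumulator_result <- function(x, ...) {
  cat("Accumulator fractions (", x$channel, " channel)\n", sep = "")
  cat("  threshold:", format(x$threshold_rpu, digits = 4), "RPU\n")
  cat("  max fraction:", format(x$max_fraction, digits = 4),
      "at t =", x$max_time_h, "h\n")
  invisible(x)
}

#' Split a sample into non-accumulator and accumulator subpopulations
#'
#' Fits a two-component Gaussian mixture to `log10` of the positive RPU
#' values (EM, via \pkg{mclust} with deterministic hierarchical
#' initialization) and hard-assigns events by maximum responsibility; the
#' component with the lower mean is the non-accumulator population. If the
#' fitted means are closer than `min_separation` decades (or the fit
#' degenerates), the sample is declared monomodal and everything is assigned
#' to the non-accumulator class.
#'
#' @param values_rpu RPU values of one sample (at least 500 events).
#' @param min_separation Minimal mean separation in decades to accept
#'   bimodality (default 0.3).
#' @return List with `non_accumulator` and `accumulator` (the input values,
#'   partitioned), `responsibility` (accumulator-class posterior per kept
#'   event), `bimodal` flag, and `means` (component means, decades).
#' @export
split_subpopulations_gmm <- function(values_rpu, min_separation = 0.3) {
  x <- values_rpu[is.finite(values_rpu) & values_rpu > 0]
  if (length(x) < 500L) stop("need at least 500 positive events")
  lx <- log10(x)
  fit <- gmm2_fit(lx)
  monomodal <- function() list(non_accumulator = x,
                               accumulator = numeric(0),
                               responsibility = rep(0, length(x)),
                               bimodal = FALSE,
                               means = NA_real_)
  if (is.null(fit) || is.null(fit$parameters)) return(monomodal())
  means <- fit$parameters$mean
  if (length(means) < 2L || abs(diff(means)) < min_separation)
    return(monomodal())
  upper <- which.max(means)
  resp <- fit$z[, upper]
  acc <- resp > 0.5              # ties (exactly 0.5) stay non-accumulator
  list(non_accumulator = x[!acc],
       accumulator = x[acc],
       responsibility = resp,
       bimodal = TRUE,
       means = sort(unname(means)))
}

# shared crossing finder: smallest x where y - y_basal >= rise, linearly
# interpolated between the bracketing measured points
net_increase_crossing <- function(x, y, rise) {
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  basal <- y[1L]
  target <- basal + rise
  above <- which(y >= target)
  if (length(above) == 0L)
    return(list(threshold = NA_real_, basal = basal))
  i <- above[1L]
  if (i == 1L) return(list(threshold = x[1L], basal = basal))
  x0 <- x[i - 1L]; y0 <- y[i - 1L]
  x1 <- x[i]; y1 <- y[i]
  thr <- if (y1 == y0) x1 else x0 + (x1 - x0) * (target - y0) / (y1 - y0)
  list(threshold = thr, basal = basal)
}

#' Induction threshold at which accumulators appear
#'
#' "Appearance" is a net increase of the maximal accumulator fraction by 5
#' percentage points over the basal level (the value at the lowest measured
#' induction). The threshold is the smallest induction where the net
#' increase reaches 5 points, linearly interpolated between the bracketing
#' measured points.
#'
#' @param curve Data.frame with columns `induction` and `max_fraction`
#'   (at least 3 points).
#' @param rise Net increase defining appearance (default 0.05).
#' @return List of class `"threshold_result"`: `induction_threshold` (may be
#'   `NA` if the rise is never reached), `basal_fraction`, `rise`.
#' @export
induction_threshold <- function(curve, rise = 0.05) {
  stopifnot(is.data.frame(curve),
            all(c("induction", "max_fraction") %in% names(curve)))
  if (nrow(curve) < 3L) stop("need at least 3 induction levels")
  cr <- net_increase_crossing(curve$induction, curve$max_fraction, rise)
  if (is.na(cr$threshold))
    warning("maximal accumulator fraction never rises ", rise,
            " above basal; threshold undefined")
  structure(list(induction_threshold = cr$threshold,
                 basal_fraction = cr$basal,
                 rise = rise, axis = "induction"),
            class = "threshold_result")
}

#' Target stress level for feedback control
#'
#' The stress (mean UPR) counterpart of [induction_threshold()]: the UPR
#' level at which the net increase of the maximal UPR-accumulator fraction
#' reaches 5 points of the population. Holding the population at this stress
#' level is the controller's reference.
#'
#' @param curve Data.frame with columns `mean_upr` and `max_fraction`.
#' @param rise Net increase defining appearance (default 0.05).
#' @return List of class `"threshold_result"` with `target_stress_rpu`.
#' @export
target_stress_level <- function(curve, rise = 0.05) {
  stopifnot(is.data.frame(curve),
            all(c("mean_upr", "max_fraction") %in% names(curve)))
  if (nrow(curve) < 3L) stop("need at least 3 stress levels")
  cr <- net_increase_crossing(curve$mean_upr, curve$max_fraction, rise)
  if (is.na(cr$threshold))
    warning("maximal accumulator fraction never rises ", rise,
            " above basal; target stress undefined")
  structure(list(target_stress_rpu = cr$threshold,
                 basal_fraction = cr$basal,
                 rise = rise, axis = "stress"),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  val <- if (x$axis == "induction") x$induction_threshold else
    x$target_stress_rpu
  cat("Accumulator-appearance threshold (", x$axis, " axis)\n", sep = "")
  cat("  basal fraction:", format(x$basal_fraction, digits = 4), "\n")
  cat("  threshold:", if (is.na(val)) "not reached" else
    format(val, digits = 4), "\n")
  invisible(x)
}

#' Infer the growth rate of the strain of interest from co-culture fractions
#'
#' In a turbidostat co-culture the dilution rate cancels from the ratio of
#' the two strains, so the log-odds of the accessory fraction changes at the
#' growth-rate difference: `d/dt log(f_a / (1 - f_a)) = mu_a - mu_i`. With
#' the accessory strain growing at a known constant rate, the strain of
#' interest's growth rate is `mu_accessory` minus the local slope, estimated
#' by centered differences over a 3-sample window.
#'
#' @param fraction_series Data.frame with columns `time_h` and `f_a`
#'   (accessory fraction, strictly inside (0, 1)).
#' @param mu_accessory Accessory-strain growth rate, per hour (> 0);
#'   typically the common pre-induction rate.
#' @return Data.frame `time_h`, `growth_rate` (per hour) at the interior
#'   points of the series; points where `f_a` touches 0 or 1 are dropped
#'   with a warning.
#' @export
infer_growth_rate <- function(fraction_series, mu_accessory) {
  stopifnot(is.data.frame(fraction_series),
            all(c("time_h", "f_a") %in% names(fraction_series)))
  if (!is.numeric(mu_accessory) || mu_accessory <= 0)
    stop("'mu_accessory' must be positive")
  fs <- fraction_series[order(fraction_series$time_h), ]
  ok <- fs$f_a > 0 & fs$f_a < 1 & is.finite(fs$f_a)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " point(s) where the accessory fraction ",
            "touches 0 or 1")
    fs <- fs[ok, , drop = FALSE]
  }
  if (nrow(fs) < 3L) stop("need at least 3 usable points")
  t <- fs$time_h
  L <- log(fs$f_a / (1 - fs$f_a))
  n <- nrow(fs)
  idx <- 2:(n - 1L)
  slope <- (L[idx + 1L] - L[idx - 1L]) / (t[idx + 1L] - t[idx - 1L])
  data.frame(time_h = t[idx], growth_rate = mu_accessory - slope)
}
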