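#' @title Event-level cytometry processing
#' @description
#' The processing chain applied to every raw event table, in this order:
#' per-experiment channel correction, forward-scatter cell gating, per-event
#' size and reference (RPU) normalization, strain demultiplexing on the
#' constitutive blue marker, and pre-induction baseline subtraction. The
#' order matters: gating precedes demultiplexing, and the blue-marker
#' thresholds are defined in the size-normalized RPU domain.
#' @name cytometry_processing
NULL

FLUOR_CHANNELS <- c("GRN_B", "BLU_V", "ORG_G")

#' Default strain-demultiplexing thresholds on the BLU-V channel (RPU):
#' events above `accessory` belong to the accessory strain, events below
#' `interest` to the strain of interest; the dead band between them is left
#' unclassified.
#' @export
blu_thresholds <- function() c(interest = 3e-2, accessory = 6e-2)

check_events <- function(events, stage = NULL) {
  if (!is.data.frame(events))
    stop("event table must be a data.frame")
  need <- c("time_h", "FSC", FLUOR_CHANNELS)
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("event table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.null(stage)) {
    have <- processing_stage(events)
    if (have != stage)
      stop("expected a '", stage, "' event table but got '", have,
           "' (tables are never silently re-processed)")
  }
  invisible(events)
}

processing_stage <- function(events) {
  st <- attr(events, "optosec_stage")
  if (is.null(st)) "raw" else st
}

set_stage <- function(events, stage) {
  attr(events, "optosec_stage") <- stage
  events
}

#' Apply per-experiment channel correction coefficients
#'
#' Day-to-day cytometer drift is corrected with per-channel multiplicative
#' coefficients measured from a calibration-bead run. Channels without a
#' supplied coefficient default to 1 with a warning.
#'
#' @param events Raw `EventTable`.
#' @param coeffs Named numeric vector of positive multipliers, names among
#'   `GRN_B`, `BLU_V`, `ORG_G`.
#' @return Corrected `EventTable` (still raw-domain).
#' @export
apply_channel_correction <- function(events, coeffs) {
  check_events(events, "raw")
  if (length(coeffs) == 0 || is.null(names(coeffs)) || any(names(coeffs) == ""))
    stop("'coeffs' must be a named numeric vector")
  unknown <- setdiff(names(coeffs), FLUOR_CHANNELS)
  if (length(unknown))
    stop("unknown channel(s) in coeffs: ", paste(unknown, collapse = ", "))
  if (any(!is.finite(coeffs)) || any(coeffs <= 0))
    stop("correction coefficients must be positive and finite")
  missing_ch <- setdiff(FLUOR_CHANNELS, names(coeffs))
  if (length(missing_ch))
    warning("no coefficient for ", paste(missing_ch, collapse = ", "),
            "; defaulting to 1")
  for (ch in names(coeffs)) events[[ch]] <- events[[ch]] * coeffs[[ch]]
  events
}

#' Gate single cells on forward scatter
#'
#' Keeps events with FSC in the closed interval `[1000, 2000]`, discarding
#' debris (small) and doublets (large).
#'
#' @param events `EventTable` with an `FSC` column.
#' @param fsc_min,fsc_max Gate bounds (defaults 1000 and 2000).
#' @return Gated `EventTable`; empty output is allowed with a warning.
#' @export
gate_cells <- function(events, fsc_min = 1000, fsc_max = 2000) {
  check_events(events)
  keep <- events$FSC >= fsc_min & events$FSC <= fsc_max
  out <- events[keep, , drop = FALSE]
  if (nrow(out) == 0L) warning("FSC gate removed all events")
  rownames(out) <- NULL
  out
}

#' Convert raw fluorescence to relative promoter units
#'
#' Each fluorescence channel is divided by the event's FSC (size
#' normalization) and by the fluorescence scale of a constitutive reference
#' strain, yielding relative promoter units. Optionally subtracts a
#' pre-induction baseline: the per-channel mean over the strain-of-interest
#' events recorded in the `baseline_window_h` hours before
#' `induction_start_h` (values may go negative after subtraction; that is
#' expected and preserved). Already-normalized tables are rejected, never
#' silently re-normalized.
#'
#' @param events Raw (corrected, gated) `EventTable`.
#' @param reference_rpu Named positive scales per channel (see
#'   [default_rpu_references()] for the emulated instrument).
#' @param induction_start_h If given, subtract the pre-induction baseline
#'   computed from this table's strain-of-interest events.
#' @param baseline Named per-channel baseline override (RPU); used instead of
#'   the window computation (required if the table has no pre-induction
#'   samples).
#' @param baseline_window_h Width of the pre-induction window (default 2 h).
#' @return `EventTable` with fluorescence channels in RPU; carries the
#'   baseline used as attribute `"baseline"`.
#' @export
to_rpu <- function(events, reference_rpu, induction_start_h = NULL,
                   baseline = NULL, baseline_window_h = 2) {
  check_events(events, "raw")
  if (!all(FLUOR_CHANNELS %in% names(reference_rpu)))
    stop("'reference_rpu' must provide scales for ",
         paste(FLUOR_CHANNELS, collapse = ", "))
  if (any(reference_rpu[FLUOR_CHANNELS] <= 0))
    stop("'reference_rpu' scales must be positive")
  for (ch in FLUOR_CHANNELS)
    events[[ch]] <- events[[ch]] / events$FSC / reference_rpu[[ch]]
  events <- set_stage(events, "rpu")
  if (is.null(induction_start_h) && is.null(baseline)) return(events)
  if (is.null(baseline)) {
    win <- events$time_h >= induction_start_h - baseline_window_h &
      events$time_h < induction_start_h
    thr <- blu_thresholds()
    interest <- win & events$BLU_V < thr[["interest"]]
    if (!any(interest))
      stop("no pre-induction strain-of-interest events for baselining; ",
           "supply a 'baseline' override")
    baseline <- vapply(FLUOR_CHANNELS,
                       function(ch) mean(events[[ch]][interest]), numeric(1L))
  }
  if (!all(FLUOR_CHANNELS %in% names(baseline)))
    stop("'baseline' must be named per channel")
  for (ch in FLUOR_CHANNELS) events[[ch]] <- events[[ch]] - baseline[[ch]]
  attr(events, "baseline") <- baseline
  set_stage(events, "rpu_baselined")
}

#' Demultiplex the co-cultured strains on the blue marker
#'
#' The accessory strain constitutively expresses a blue fluorescent marker;
#' events with size-normalized BLU-V above the accessory threshold are
#' accessory cells, events below the interest threshold are cells of the
#' strain of interest, and events in the dead band are left unclassified and
#' excluded from both strains' statistics (this avoids cross-contaminating
#' the red-channel statistics of either strain).
#'
#' @param events RPU-domain `EventTable` (before baseline subtraction the
#'   thresholds are on the absolute marker level; [process_events()] splits
#'   before baselining).
#' @param thresholds Named vector `c(interest=, accessory=)`, defaults
#'   [blu_thresholds()].
#' @return List of `EventTable`s: `interest`, `accessory`, `unclassified`.
#' @export
split_strains <- function(events, thresholds = blu_thresholds()) {
  check_events(events)
  if (processing_stage(events) == "raw")
    stop("strain thresholds are defined on size-normalized RPU values; ",
         "run to_rpu() first")
  stopifnot(all(c("interest", "accessory") %in% names(thresholds)),
            thresholds[["interest"]] <= thresholds[["accessory"]])
  is_acc <- events$BLU_V > thresholds[["accessory"]]
  is_int <- events$BLU_V < thresholds[["interest"]]
  split_tab <- function(keep) {
    out <- events[keep, , drop = FALSE]
    rownames(out) <- NULL
    set_stage(out, processing_stage(events))
  }
  list(interest = split_tab(is_int),
       accessory = split_tab(is_acc),
       unclassified = split_tab(!is_acc & !is_int))
}

#' Subtract a pre-induction baseline from RPU channels
#'
#' @param events RPU-domain `EventTable`.
#' @param baseline Named per-channel baseline (RPU).
#' @return Baseline-subtracted table (values may be negative).
#' @export
subtract_baseline <- function(events, baseline) {
  check_events(events, "rpu")
  if (!all(FLUOR_CHANNELS %in% names(baseline)))
    stop("'baseline' must be named per channel")
  for (ch in FLUOR_CHANNELS) events[[ch]] <- events[[ch]] - baseline[[ch]]
  attr(events, "baseline") <- baseline
  set_stage(events, "rpu_baselined")
}

#' Normalized induction level from accessory-strain red fluorescence
#'
#' The accessory strain expresses a red reporter under the same light-driven
#' promoter as the protein of interest, so its steady-state red level reports
#' the induction actually delivered to a reactor. Dividing by the maximal
#' accessory red level observed across all experiments puts induction on a
#' common `[0, 1]` scale.
#'
#' @param accessory_org_rpu Baseline-subtracted ORG-G RPU values of accessory
#'   events at (quasi) steady state.
#' @param global_max_rpu Maximal accessory red level across the experiment
#'   campaign (positive).
#' @return Normalized induction in `[0, 1]`; `NA` with a warning for an
#'   empty sample.
#' @export
induction_level <- function(accessory_org_rpu, global_max_rpu) {
  if (!is.numeric(global_max_rpu) || global_max_rpu <= 0)
    stop("'global_max_rpu' must be positive")
  x <- accessory_org_rpu[is.finite(accessory_org_rpu)]
  if (length(x) == 0L) {
    warning("no accessory events; induction level undefined")
    return(NA_real_)
  }
  min(max(mean(x) / global_max_rpu, 0), 1)
}

#' Summarize one processed sample
#'
#' Computes the per-timepoint population statistics used throughout the
#' analysis: the median internal protein level (iPOI, GRN-B) and the mean and
#' median UPR reporter level (ORG-G) of the strain of interest, the strain
#' fractions, and the accessory-strain red level. The mean UPR is what the
#' feedback controller consumes (a plate reader could supply it); the median
#' is retained for distribution-shape diagnostics.
#'
#' @param interest,accessory Baseline-subtracted strain tables from
#'   [split_strains()].
#' @param n_unclassified Number of dead-band events (for count bookkeeping).
#' @param n_events_total,n_after_gate Optional acquisition counts.
#' @return One-row data.frame (`SampleSummary`).
#' @export
summarize_sample <- function(interest, accessory, n_unclassified = 0L,
                             n_events_total = NA_integer_,
                             n_after_gate = NA_integer_) {
  n_int <- nrow(interest); n_acc <- nrow(accessory)
  if (is.na(n_after_gate)) n_after_gate <- n_int + n_acc + n_unclassified
  time_h <- if (n_int > 0) interest$time_h[1L] else if (n_acc > 0)
    accessory$time_h[1L] else NA_real_
  if (n_int == 0L)
    warning("no strain-of-interest events; POI statistics are missing")
  data.frame(
    time_h = time_h,
    n_events_total = n_events_total,
    n_after_gate = n_after_gate,
    n_interest = n_int,
    n_accessory = n_acc,
    n_unclassified = n_unclassified,
    fraction_interest = if (n_int + n_acc > 0) n_int / (n_int + n_acc)
      else NA_real_,
    median_iPOI_rpu = if (n_int > 0) stats::median(interest$GRN_B) else NA_real_,
    mean_upr_rpu = if (n_int > 0) mean(interest$ORG_G) else NA_real_,
    median_upr_rpu = if (n_int > 0) stats::median(interest$ORG_G) else NA_real_,
    induction_rpu = if (n_acc > 0) mean(accessory$ORG_G) else NA_real_
  )
}

#' Run the full event-processing chain on a timestamped event table
#'
#' Correction, FSC gating, RPU normalization, strain splitting, pre-induction
#' baseline subtraction (per strain, from that strain's own pre-induction
#' events), and per-timepoint summarization.
#'
#' @param events Raw `EventTable` covering one reactor run (multiple sample
#'   times).
#' @param coeffs Channel-correction coefficients (default: identity).
#' @param reference_rpu Per-channel RPU reference scales.
#' @param induction_start_h Time light induction started (baseline window is
#'   the 2 h before it).
#' @param baseline_window_h Baseline window width (default 2).
#' @param thresholds BLU-V demultiplexing thresholds.
#' @return List with `summaries` (one `SampleSummary` row per time),
#'   `interest`, `accessory`, `unclassified` (processed tables),
#'   `baseline` (per-strain per-channel values), and `log` (per-stage event
#'   counts).
#' @export
process_events <- function(events,
                           coeffs = c(GRN_B = 1, BLU_V = 1, ORG_G = 1),
                           reference_rpu = default_rpu_references(),
                           induction_start_h,
                           baseline_window_h = 2,
                           thresholds = blu_thresholds()) {
  check_events(events, "raw")
  n_total <- nrow(events)
  ev <- apply_channel_correction(events, coeffs)
  ev <- gate_cells(ev)
  n_gated <- nrow(ev)
  ev <- to_rpu(ev, reference_rpu)
  parts <- split_strains(ev, thresholds)

  win <- function(tab) tab$time_h >= induction_start_h - baseline_window_h &
    tab$time_h < induction_start_h
  baseline_of <- function(tab) {
    w <- win(tab)
    if (!any(w))
      stop("no pre-induction events for baselining (induction_start_h = ",
           induction_start_h, ")")
    vapply(FLUOR_CHANNELS, function(ch) mean(tab[[ch]][w]), numeric(1L))
  }
  bl_int <- baseline_of(parts$interest)
  bl_acc <- baseline_of(parts$accessory)
  interest <- subtract_baseline(parts$interest, bl_int)
  accessory <- subtract_baseline(parts$accessory, bl_acc)

  times <- sort(unique(events$time_h))
  summaries <- do.call(rbind, lapply(times, function(tt) {
    s <- summarize_sample(
      interest[interest$time_h == tt, , drop = FALSE],
      accessory[accessory$time_h == tt, , drop = FALSE],
      n_unclassified = sum(parts$unclassified$time_h == tt),
      n_events_total = sum(events$time_h == tt))
    s$time_h <- tt
    s$n_after_gate <- s$n_interest + s$n_accessory + s$n_unclassified
    s
  }))
  rownames(summaries) <- NULL
  list(summaries = summaries,
       interest = interest,
       accessory = accessory,
       unclassified = parts$unclassified,
       baseline = list(interest = bl_int, accessory = bl_acc),
       log = data.frame(stage = c("input", "fsc_gate"),
                        n_events = c(n_total, n_gated)))
}
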