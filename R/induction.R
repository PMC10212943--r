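#' Piecewise-constant light induction profile
#'
#' Optogenetic induction is encoded as a light duty cycle: the fraction of a
#' fixed period (30 min for open-loop characterization, 45 min for closed-loop
#' control, matching the cytometry sampling period) during which the blue LED
#' is on. A profile is a right-continuous step function of time: duty
#' `duties[i]` applies on `[breakpoints[i], breakpoints[i+1])` and the last
#' duty is held indefinitely.
#'
#' @param breakpoints Strictly increasing times in hours at which the duty
#'   changes. The profile is undefined before the first breakpoint.
#' @param duties Duty values in `[0, 1]`, one per breakpoint.
#' @param period_min Light-encoding period in minutes (default 30, the
#'   characterization period; closed-loop control uses 45).
#' @return An object of class `"induction_profile"`.
#' @examples
#' prof <- induction_profile(c(0, 3), c(0, 1))
#' induction_at(prof, c(2.9, 3, 10))
#' @export
induction_profile <- function(breakpoints, duties, period_min = 30) {
  breakpoints <- as.numeric(breakpoints)
  duties <- as.numeric(duties)
  if (length(breakpoints) == 0L || length(breakpoints) != length(duties))
    stop("'breakpoints' and 'duties' must be non-empty and of equal length")
  if (any(!is.finite(breakpoints)) || any(diff(breakpoints) <= 0))
    stop("'breakpoints' must be finite and strictly increasing")
  if (any(!is.finite(duties)) || any(duties < 0) || any(duties > 1))
    stop("'duties' must lie in [0, 1]")
  if (!is.numeric(period_min) || length(period_min) != 1L || period_min <= 0)
    stop("'period_min' must be a single positive number")
  structure(
    list(breakpoints = breakpoints, duties = duties, period_min = period_min),
    class = "induction_profile"
  )
}

#' Constant induction profile
#'
#' @param duty Duty in `[0, 1]`.
#' @param from Start time in hours (default 0).
#' @param period_min Light-encoding period in minutes.
#' @return An `induction_profile` holding `duty` from `from` onwards.
#' @export
constant_induction <- function(duty, from = 0, period_min = 30) {
  induction_profile(from, duty, period_min = period_min)
}

#' Evaluate an induction profile
#'
#' Returns the duty of the interval containing `t`. The profile is
#' right-continuous at breakpoints and holds its last value beyond the final
#' breakpoint; times before the first breakpoint are an error (the light
#' schedule is undefined there).
#'
#' @param profile An [induction_profile()].
#' @param t Times in hours (vectorized).
#' @return Numeric vector of duties in `[0, 1]`.
#' @export
induction_at <- function(profile, t) {
  stopifnot(inherits(profile, "induction_profile"))
  t <- as.numeric(t)
  if (any(!is.finite(t))) stop("'t' must be finite")
  if (any(t < profile$breakpoints[1L]))
    stop("induction schedule undefined before first breakpoint (t = ",
         profile$breakpoints[1L], " h)")
  idx <- findInterval(t, profile$breakpoints)
  profile$duties[idx]
}

#' @export
print.induction_profile <- function(x, ...) {
  cat("Induction profile (", length(x$breakpoints), " segment",
      if (length(x$breakpoints) > 1L) "s", ", period ",
      x$period_min, " min)\n", sep = "")
  seg <- data.frame(from_h = x$breakpoints, duty = x$duties)
  print(seg, row.names = FALSE)
  invisible(x)
}
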