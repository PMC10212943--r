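#' Rate constants of the three-state secretion model
#'
#' The deterministic model tracks a production intermediate `Prd` (typically
#' the mRNA of the protein of interest), the protein in traffic `Trf` (in the
#' secretory compartments, measured as internal fluorescence in relative
#' promoter units, RPU), and the secreted protein `Sec` in the culture media:
#'
#' \deqn{dPrd/dt = K_{prd} \cdot Ind - K_{prd} \cdot Prd}
#' \deqn{dTrf/dt = K_{trf} \cdot Prd - (K_{sec} + K_{deg} + K_{dil}) \cdot Trf}
#' \deqn{dSec/dt = K_{sec} \cdot K_{units} \cdot Trf - K_{dil} \cdot Sec}
#'
#' `Ind` is the normalized induction level in `[0, 1]`. Production and
#' degradation of the intermediate share one constant (`Kprd`) because the two
#' are not separately identifiable from fluorescence data. `Kdil` is shared
#' between cell growth and media renewal: in turbidostat operation the
#' dilution rate equals the population growth rate. `Kunits` converts internal
#' fluorescence units to the secreted (bead-assay) scale.
#'
#' @param Kprd Intermediate production/turnover rate, per hour.
#' @param Ktrf Translation/translocation rate into the secretory pathway, per hour.
#' @param Ksec Secretion rate, per hour.
#' @param Kdeg Active degradation rate (e.g. ER-associated degradation), per hour.
#' @param Kdil Dilution rate = growth rate = media renewal rate, per hour.
#' @param Kunits Internal-to-secreted fluorescence scale, dimensionless, > 0.
#' @return A named list of class `"model_params"`.
#' @export
model_params <- function(Kprd, Ktrf, Ksec = 0, Kdeg = 0, Kdil = 0, Kunits = 1) {
  p <- list(Kprd = Kprd, Ktrf = Ktrf, Ksec = Ksec, Kdeg = Kdeg,
            Kdil = Kdil, Kunits = Kunits)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number")
  }
  rates <- c("Kprd", "Ktrf", "Ksec", "Kdeg", "Kdil")
  if (any(unlist(p[rates]) < 0)) stop("rate constants must be non-negative")
  if (p$Kunits <= 0) stop("'Kunits' must be strictly positive")
  structure(lapply(p, as.numeric), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Three-state secretion model parameters (per hour; Kunits dimensionless):\n")
  print(unlist(x))
  invisible(x)
}

#' @export
as.list.model_params <- function(x, ...) unclass(x)

ode_rhs <- function(t, y, parms) {
  ind <- parms$ind
  with(parms$p, {
    dPrd <- Kprd * ind - Kprd * y[1L]
    dTrf <- Ktrf * y[1L] - (Ksec + Kdeg + Kdil) * y[2L]
    dSec <- Ksec * Kunits * y[2L] - Kdil * y[3L]
    list(c(dPrd, dTrf, dSec))
  })
}

#' Simulate the three-state secretion model
#'
#' Integrates the model on a time grid under a piecewise-constant induction
#' profile. The induction duty is used directly as the normalized induction
#' `Ind` in `[0, 1]`. Integration is adaptive (lsoda, stiff-capable) and is
#' performed interval-by-interval between induction breakpoints so that the
#' step discontinuities are never smeared by the step-size controller.
#'
#' @param params A [model_params()] object.
#' @param profile An [induction_profile()], or a single duty in `[0, 1]`
#'   (treated as constant induction from the first grid time).
#' @param times Increasing time grid in hours.
#' @param init Initial state `c(Prd, Trf, Sec)`, non-negative. Defaults to the
#'   zero state: processed fluorescence data are baseline-subtracted, so
#'   trajectories start at zero at induction start.
#' @param rtol,atol Solver tolerances.
#' @return A data.frame with columns `time_h`, `Prd`, `Trf`, `Sec`. States are
#'   clipped to zero from below (values above `-1e-9` only; larger negative
#'   values would indicate solver failure and raise an error).
#' @examples
#' p <- model_params(Kprd = 2, Ktrf = 1, Ksec = 0.3, Kdeg = 0.1, Kdil = 0.46)
#' traj <- simulate_ode(p, constant_induction(1), seq(0, 24, by = 0.75))
#' head(traj)
#' @export
simulate_ode <- function(params, profile, times, init = c(0, 0, 0),
                         rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  if (is.numeric(profile) && length(profile) == 1L)
    profile <- constant_induction(profile, from = times[1L])
  stopifnot(inherits(profile, "induction_profile"))
  times <- as.numeric(times)
  if (length(times) < 2L || any(diff(times) <= 0))
    stop("'times' must be an increasing grid with at least two points")
  init <- as.numeric(init)
  if (length(init) != 3L || any(!is.finite(init)) || any(init < 0))
    stop("'init' must be three finite non-negative values")

  # segment the grid at induction breakpoints interior to the horizon
  bp <- profile$breakpoints
  cuts <- bp[bp > times[1L] & bp < times[length(times)]]
  edges <- sort(unique(c(times[1L], cuts, times[length(times)])))

  y <- init
  out_t <- times[1L]
  out_y <- matrix(y, nrow = 1L)
  for (k in seq_len(length(edges) - 1L)) {
    a <- edges[k]; b <- edges[k + 1L]
    ind <- induction_at(profile, a)  # right-continuous: duty on [a, b)
    seg_t <- unique(c(a, times[times > a & times < b], b))
    sol <- deSolve::ode(y = y, times = seg_t, func = ode_rhs,
                        parms = list(p = params, ind = ind),
                        method = "lsoda", rtol = rtol, atol = atol)
    if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1L] < 0)
      stop("ODE solver failed on segment [", a, ", ", b, "] h (istate = ",
           attr(sol, "istate")[1L], ")")
    y <- as.numeric(sol[nrow(sol), 2:4])
    keep <- sol[, 1L] %in% times & sol[, 1L] > out_t[length(out_t)]
    if (any(keep)) {
      out_t <- c(out_t, sol[keep, 1L])
      out_y <- rbind(out_y, sol[keep, 2:4, drop = FALSE])
    }
  }
  if (min(out_y) < -1e-9)
    stop("solver produced substantially negative states (min = ",
         format(min(out_y)), ")")
  out_y[out_y < 0] <- 0
  res <- data.frame(time_h = out_t, Prd = out_y[, 1L], Trf = out_y[, 2L],
                    Sec = out_y[, 3L])
  # initial grid time may not be the first output row if times[1] < first edge
  res[match(times, res$time_h), , drop = FALSE]
}

#' Steady state of the secretion model at constant induction
#'
#' Closed-form fixed point of the model equations:
#' `Prd* = ind`, `Trf* = Ktrf * ind / (Ksec + Kdeg + Kdil)`,
#' `Sec* = Ksec * Kunits * Trf* / Kdil`.
#'
#' @param params A [model_params()] object with `Ksec + Kdeg + Kdil > 0` and
#'   `Kdil > 0` (the secreted pool has no fixed point without media turnover).
#' @param ind Constant induction duty in `[0, 1]`.
#' @return Named numeric vector `c(Prd, Trf, Sec)`.
#' @export
steady_state <- function(params, ind) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(ind) || length(ind) != 1L || ind < 0 || ind > 1)
    stop("'ind' must be a single duty in [0, 1]")
  out <- params$Ksec + params$Kdeg + params$Kdil
  if (out <= 0) stop("Ksec + Kdeg + Kdil must be positive for a Trf fixed point")
  if (params$Kdil <= 0 && params$Ksec > 0)
    stop("Kdil must be positive for a Sec fixed point (turbidostat media turnover)")
  trf <- params$Ktrf * ind / out
  sec <- if (params$Ksec == 0) 0 else params$Ksec * params$Kunits * trf / params$Kdil
  c(Prd = ind, Trf = trf, Sec = sec)
}
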