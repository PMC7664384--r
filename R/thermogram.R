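#' Construct a thermogram
#'
#' A thermogram is the power-vs-time record of an ITC experiment. The sign
#' convention used throughout is that the reaction contribution to `power`
#' is positive, so integrated heats and reaction enthalpies come out
#' positive; the raw instrument polarity, if known, can be recorded in
#' `meta$endothermic`.
#'
#' @param time sample times, s (strictly increasing, length >= 3).
#' @param power net heat production rate, W.
#' @param temperature cell temperature, K.
#' @param injection_time time of the main injection, s.
#' @param meta free-form provenance list.
#' @return object of class `thermogram` (a data frame with columns `time`
#'   and `power` and attributes `temperature`, `injection_time`, `meta`).
#' @export
thermogram <- function(time, power, temperature, injection_time = 0,
                       meta = list()) {
  if (length(time) != length(power) || length(time) < 3) {
    stop("time and power must have equal length >= 3")
  }
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!all(is.finite(power))) stop("power values must be finite")
  structure(data.frame(time = time, power = power),
            temperature = temperature,
            injection_time = injection_time,
            meta = meta,
            class = c("thermogram", "data.frame"))
}

#' @export
print.thermogram <- function(x, ...) {
  cat(sprintf(
    "<thermogram> %d samples, t = [%.1f, %.1f] s, T = %.2f K\n",
    nrow(x), min(x$time), max(x$time), attr(x, "temperature")))
  invisible(x)
}

#' Subtract reference (dilution / blank) thermograms
#'
#' Subtracts one or two reference signals (e.g. titrant-into-buffer for the
#' heat of dilution, buffer-into-enzyme for the injection blank) from a raw
#' measurement, after linear interpolation of each reference onto the raw
#' time grid. Linear interpolation is used deliberately; spline
#' interpolation can ring at the sharp injection spike.
#'
#' @param raw the measurement `thermogram`.
#' @param references a single `thermogram` or a list of one or two.
#' @return net `thermogram`; `meta$references_applied` records how many.
#' @export
subtract_reference <- function(raw, references) {
  stopifnot(inherits(raw, "thermogram"))
  if (inherits(references, "thermogram")) references <- list(references)
  if (!length(references) %in% c(1L, 2L)) {
    stop("supply one or two reference thermograms")
  }
  net <- raw$power
  for (ref in references) {
    stopifnot(inherits(ref, "thermogram"))
    if (abs(attr(ref, "temperature") - attr(raw, "temperature")) > 0.1) {
      stop("reference temperature differs from measurement by > 0.1 K")
    }
    if (max(ref$time) < min(raw$time) || min(ref$time) > max(raw$time)) {
      stop("reference and measurement time ranges do not overlap")
    }
    net <- net - stats::approx(ref$time, ref$power, xout = raw$time,
                               rule = 2)$y
  }
  meta <- attr(raw, "meta")
  meta$references_applied <- length(references)
  thermogram(raw$time, net, attr(raw, "temperature"),
             attr(raw, "injection_time"), meta)
}

#' Integrate heat over a time window
#'
#' Composite trapezoidal integral of power over `[t_start, t_end]`, with
#' linearly interpolated values at the window edges so that the integral is
#' exactly additive over adjacent windows.
#'
#' @param tg a `thermogram`.
#' @param t_start,t_end integration window, s (defaults: full record).
#' @return heat, J.
#' @export
integrate_heat <- function(tg, t_start = min(tg$time),
                           t_end = max(tg$time)) {
  stopifnot(inherits(tg, "thermogram"))
  if (t_start >= t_end) stop("t_start must be < t_end")
  if (t_start < min(tg$time) || t_end > max(tg$time)) {
    stop("integration window outside the recorded time range")
  }
  inside <- tg$time > t_start & tg$time < t_end
  tt <- c(t_start, tg$time[inside], t_end)
  pp <- stats::approx(tg$time, tg$power, xout = tt)$y
  pracma::trapz(tt, pp)
}

#' Convert a thermogram to a concentration / rate trace
#'
#' The single-injection progress-curve transform: the substrate consumption
#' rate is read directly from the power,
#' `r(t) = P(t) / (dH * m)`, and the substrate molality follows from the
#' running heat integral,
#' `cS(t) = cS0 - cumint(P) / (dH * m)`.
#' The driving force column is left `NA` until an equilibrium state is
#' attached by [apply_trim_rules()].
#'
#' @param tg a `thermogram` whose time origin is the start of the reaction
#'   (references and baseline already subtracted).
#' @param delta_h molar reaction enthalpy, J mol^-1 (non-zero).
#' @param m solution mass in the cell, kg.
#' @param cS0 initial substrate molality, mol kg^-1.
#' @return object of class `kinetic_trace`: data frame with columns
#'   `time`, `cS`, `r`, `iota`, `included`, and attributes `cS0`,
#'   `temperature`.
#' @export
to_concentration_trace <- function(tg, delta_h, m, cS0) {
  stopifnot(inherits(tg, "thermogram"), delta_h != 0, m > 0, cS0 > 0)
  scale <- delta_h * m
  q_cum <- pracma::cumtrapz(tg$time, tg$power)[, 1]
  cS <- cS0 - q_cum / scale
  if (any(cS < 0)) {
    t_bad <- tg$time[which(cS < 0)[1]]
    stop(sprintf(paste0(
      "substrate molality becomes negative at t = %.6g s; check delta_h, ",
      "m, cS0 or un-subtracted dilution heat"), t_bad))
  }
  kinetic_trace(tg$time, cS, tg$power / scale,
                cS0 = cS0, temperature = attr(tg, "temperature"))
}

#' Construct a kinetic trace
#'
#' @param time sample times, s.
#' @param cS substrate molality, mol kg^-1.
#' @param r substrate consumption rate, mol kg^-1 s^-1.
#' @param iota driving force (optional; `NA` until attached).
#' @param included logical fitting mask.
#' @param cS0 initial substrate molality, mol kg^-1.
#' @param temperature K.
#' @return object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, cS, r, iota = NA_real_,
                          included = TRUE, cS0, temperature = NA_real_) {
  structure(data.frame(time = time, cS = cS, r = r, iota = iota,
                       included = included),
            cS0 = cS0, temperature = temperature,
            class = c("kinetic_trace", "data.frame"))
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf(
    "<kinetic_trace> %d samples (%d included), cS in [%.4g, %.4g] mol/kg\n",
    nrow(x), sum(x$included), min(x$cS), max(x$cS)))
  invisible(x)
}

#' Apply the fitting-window trim rules
#'
#' Two rules restrict which samples enter the kinetic fits. First, all
#' points at or before the time of maximum |rate| are excluded: the early
#' signal is dominated by instrument inertia and the heat of dilution, not
#' reaction kinetics. Second, in flux-force mode, points with
#' `iota / (2 - iota) > 0.6` are excluded (equality is kept), because the
#' linear flux-force relation holds near equilibrium only; this corresponds
#' to dropping all points with `iota > 0.75`. The driving force column is
#' filled from the attached equilibrium state.
#'
#' @param trace a `kinetic_trace`.
#' @param eq an `equilibrium_state`.
#' @param flux_force_mode apply the near-equilibrium threshold?
#' @return the trace with `iota` filled and `included` updated (points are
#'   only ever removed, never re-added).
#' @export
apply_trim_rules <- function(trace, eq, flux_force_mode = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"),
            inherits(eq, "equilibrium_state"))
  cS0 <- attr(trace, "cS0")
  iota <- driving_force(trace$cS, cS0 - trace$cS, eq)
  included <- trace$included
  i_max <- which.max(abs(trace$r))
  included[seq_len(i_max)] <- FALSE
  if (flux_force_mode) {
    included <- included & !(iota / (2 - iota) > 0.6)
  }
  if (sum(included) < 5) {
    stop("fewer than 5 points remain after trimming; trace is unfittable")
  }
  out <- trace
  out$iota <- iota
  out$included <- included
  out
}
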