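#' Configuration for a synthetic ITC experiment
#'
#' Bundles a ground-truth kinetic model, the reaction context and the
#' instrument model for generating synthetic single-injection thermograms.
#' The instrument model comprises a first-order response (time constant
#' `tau_instrument`), an additive Gaussian dilution pulse at the injection,
#' and i.i.d. Gaussian baseline noise.
#'
#' Defaults for `tau_instrument` (10 s) and `noise_sd` (0.02 uW) are
#' engineering choices on the scale of modern titration calorimeters;
#' published thermograms of these reactions are consistent with that scale
#' but the instrument constants themselves are not reported, so both are
#' overridable.
#'
#' @param model_kind `"flux_force"`, `"noor_substrate"` or
#'   `"noor_product"`.
#' @param true_params matching parameter object ([flux_force_params()],
#'   [noor_substrate_params()] or [noor_product_params()]).
#' @param reaction a [reaction_system()].
#' @param duration total record length, s.
#' @param dt output sampling interval, s.
#' @param tau_instrument first-order instrument time constant, s (>= 0).
#' @param noise_sd baseline noise standard deviation, W (>= 0).
#' @param dilution_heat total heat of the dilution pulse, J.
#' @param dilution_width standard deviation of the Gaussian pulse, s.
#' @param injection_time injection time, s (0 <= injection_time < duration).
#' @param seed integer seed for the noise generator (`NULL` = leave RNG
#'   state alone).
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(model_kind = c("flux_force",
                                             "noor_substrate",
                                             "noor_product"),
                              true_params, reaction,
                              duration, dt,
                              tau_instrument = 10,
                              noise_sd = 2e-8,
                              dilution_heat = 0,
                              dilution_width = 5,
                              injection_time = 0,
                              seed = NULL) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(reaction, "reaction_system"),
            is.numeric(duration), is.numeric(dt))
  if (dt <= 0) stop("dt must be > 0")
  if (!(duration > injection_time && injection_time >= 0)) {
    stop("require duration > injection_time >= 0")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (tau_instrument < 0) stop("tau_instrument must be >= 0")
  expected <- switch(model_kind,
                     flux_force = "flux_force_params",
                     noor_substrate = "noor_substrate_params",
                     noor_product = "noor_product_params")
  if (!inherits(true_params, expected)) {
    stop(sprintf("true_params must be a %s for model_kind '%s'",
                 expected, model_kind))
  }
  structure(list(model_kind = model_kind, true_params = true_params,
                 reaction = reaction, duration = duration, dt = dt,
                 tau_instrument = tau_instrument, noise_sd = noise_sd,
                 dilution_heat = dilution_heat,
                 dilution_width = dilution_width,
                 injection_time = injection_time, seed = seed),
            class = "simulation_config")
}

# Rate of substrate consumption as a function of cS, under the mass
# balance cP = cS0 - cS, for the configured ground-truth model.
.rate_function <- function(config, eq) {
  p <- config$true_params
  cS0 <- config$reaction$cS0
  switch(config$model_kind,
    flux_force = function(cS) {
      flux_force_rate(p, driving_force(cS, cS0 - cS, eq))
    },
    noor_substrate = function(cS) noor_rate_substrate(p, cS, cS0, eq),
    noor_product = function(cS) noor_rate_product(p, cS, cS0, eq))
}

#' Simulate a reaction progress curve
#'
#' Integrates `dcS/dt = -r(cS)` for the configured ground-truth rate law
#' from `cS(0) = cS0` on a uniform output grid (adaptive-step lsoda
#' internally, rtol 1e-9, atol 1e-12; the right-hand sides are smooth and
#' non-stiff at the parameter scales of interest). The returned rate column
#' is the model rate law evaluated at the solution, not a numerical
#' derivative, and the driving force is evaluated from the solution with
#' round-off clipped to `[0, 1]`.
#'
#' @param config a [simulation_config()].
#' @return a `kinetic_trace` on `seq(0, duration - injection_time, dt)`
#'   (time measured from the injection).
#' @export
simulate_progress <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  rs <- config$reaction
  eq <- equilibrium_concentrations(rs)
  rate <- .rate_function(config, eq)
  r0 <- rate(rs$cS0)
  if (!is.finite(r0) || r0 <= 0) {
    stop("ground-truth parameters imply a non-positive initial rate")
  }
  times <- seq(0, config$duration - config$injection_time, by = config$dt)
  sol <- deSolve::ode(
    y = c(cS = rs$cS0), times = times,
    func = function(t, y, parms) list(-rate(y[[1]])),
    rtol = 1e-9, atol = 1e-12, method = "lsoda")
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(times)) {
    t_fail <- if (nrow(sol) > 0) sol[nrow(sol), 1] else 0
    stop(sprintf("ODE integration failed near t = %.6g s", t_fail))
  }
  # clip integrator round-off: cS non-increasing, bounded by [cSeq, cS0]
  cS <- pmin(cummin(sol[, "cS"]), rs$cS0)
  r <- pmax(rate(cS), 0)
  iota <- pmin(pmax(driving_force(cS, rs$cS0 - cS, eq), 0), 1)
  kinetic_trace(times, cS, r, iota = iota, included = TRUE,
                cS0 = rs$cS0, temperature = rs$temperature)
}

#' Simulate a thermogram from a progress curve
#'
#' Maps a kinetic trace to the ideal reaction power
#' `P_ideal(t) = r(t) * dH * m`, then applies the instrument model: an
#' exact first-order low-pass (time constant `tau_instrument`, unit gain,
#' implemented as the closed-form response to piecewise-linear input so
#' that the integrated heat is conserved), an additive Gaussian dilution
#' pulse of total area `dilution_heat` centred at the injection, and
#' i.i.d. Gaussian noise of standard deviation `noise_sd`.
#'
#' @param trace a `kinetic_trace` from [simulate_progress()] (time
#'   measured from the injection).
#' @param reaction the [reaction_system()].
#' @param delta_h molar reaction enthalpy, J mol^-1 (non-zero).
#' @param config the [simulation_config()].
#' @return a `thermogram` on `seq(0, duration, dt)` with ground-truth
#'   metadata in `meta`.
#' @export
simulate_thermogram <- function(trace, reaction, delta_h, config) {
  stopifnot(inherits(trace, "kinetic_trace"),
            inherits(reaction, "reaction_system"),
            inherits(config, "simulation_config"))
  if (delta_h == 0) stop("delta_h must be non-zero")
  dt <- config$dt
  tau <- config$tau_instrument
  if (tau > 0 && dt > tau / 2) {
    warning(sprintf(
      "dt = %.3g s is coarse relative to tau_instrument = %.3g s", dt, tau))
  }
  tgrid <- seq(0, config$duration, by = dt)
  t_rel <- tgrid - config$injection_time
  x <- rep(0, length(tgrid))
  on_grid <- t_rel >= 0
  x[on_grid] <- stats::approx(trace$time, trace$r, xout = t_rel[on_grid],
                              rule = 2)$y * delta_h * reaction$m
  if (tau > 0) {
    y <- .first_order_response(x, dt, tau)
  } else {
    y <- x
  }
  if (config$dilution_heat != 0) {
    y <- y + config$dilution_heat *
      stats::dnorm(tgrid, mean = config$injection_time,
                   sd = config$dilution_width)
  }
  if (config$noise_sd > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    y <- y + stats::rnorm(length(y), sd = config$noise_sd)
  }
  thermogram(tgrid, y, temperature = reaction$temperature,
             injection_time = config$injection_time,
             meta = list(synthetic = TRUE,
                         model_kind = config$model_kind,
                         delta_h = delta_h, m = reaction$m,
                         cS0 = reaction$cS0, cE = reaction$cE,
                         tau_instrument = tau,
                         noise_sd = config$noise_sd,
                         dilution_heat = config$dilution_heat,
                         seed = config$seed))
}

# Exact response of tau * y' = x - y, y(0) = 0, to a piecewise-linear
# input sampled on a uniform grid. Unit DC gain, so the integrated output
# equals the integrated input once both have returned to zero.
.first_order_response <- function(x, dt, tau) {
  n <- length(x)
  y <- numeric(n)
  a <- exp(-dt / tau)
  for (i in 2:n) {
    s <- (x[i] - x[i - 1]) / dt
    y[i] <- x[i] - tau * s + (y[i - 1] - x[i - 1] + tau * s) * a
  }
  y
}

#' Write / read a thermogram as CSV plus JSON sidecar
#'
#' The CSV has columns `time_s`, `power_W`; the sidecar (`<path>.json`)
#' stores `temperature_K`, `injection_time_s` and any scalar metadata
#' (`m_kg`, `cE_mol_per_kg`, `cS0_mol_per_kg`, ...).
#'
#' @param tg a `thermogram`.
#' @param path CSV file path.
#' @return `write_thermogram`: the path, invisibly. `read_thermogram`: a
#'   `thermogram`.
#' @export
write_thermogram <- function(tg, path) {
  stopifnot(inherits(tg, "thermogram"))
  utils::write.csv(data.frame(time_s = tg$time, power_W = tg$power),
                   path, row.names = FALSE)
  meta <- attr(tg, "meta")
  sidecar <- c(list(temperature_K = attr(tg, "temperature"),
                    injection_time_s = attr(tg, "injection_time")),
               list(m_kg = meta$m, cE_mol_per_kg = meta$cE,
                    cS0_mol_per_kg = meta$cS0))
  sidecar <- sidecar[!vapply(sidecar, is.null, logical(1))]
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thermogram
#' @export
read_thermogram <- function(path) {
  d <- utils::read.csv(path)
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path)) {
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  } else {
    list()
  }
  thermogram(d$time_s, d$power_W,
             temperature = meta$temperature_K %||% NA_real_,
             injection_time = meta$injection_time_s %||% 0,
             meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
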