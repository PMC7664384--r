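#' Fit the flux-force relation to a trimmed trace
#'
#' Linear regression of the rate against `x = iota / (2 - iota)` with the
#' intercept fixed at zero, since the rate law `r = L * cE * x` vanishes
#' exactly at equilibrium. The phenomenological coefficient is
#' `L = slope / cE`. R-squared is computed against the zero-intercept
#' model and the p-value is the t-test of the slope against zero with
#' `n - 1` degrees of freedom. A free-intercept variant is available for
#' sensitivity checks.
#'
#' @param trace a `kinetic_trace` trimmed with
#'   `apply_trim_rules(..., flux_force_mode = TRUE)`.
#' @param cE enzyme molality, mol kg^-1.
#' @param intercept fit a free intercept instead (sensitivity option)?
#' @return object of class `flux_force_fit`: list with `L`, `L_stderr`,
#'   `r_squared`, `p_value_slope`, `n_points`, `flagged` (TRUE when the
#'   slope is non-positive), `intercept`.
#' @export
fit_flux_force <- function(trace, cE, intercept = FALSE) {
  stopifnot(inherits(trace, "kinetic_trace"), cE > 0)
  keep <- trace$included & is.finite(trace$iota) & is.finite(trace$r)
  if (sum(keep) < 5) stop("fewer than 5 included points; cannot fit")
  d <- data.frame(r = trace$r[keep],
                  x = trace$iota[keep] / (2 - trace$iota[keep]))
  fit <- if (intercept) stats::lm(r ~ x, data = d) else
    stats::lm(r ~ 0 + x, data = d)
  sm <- summary(fit)
  ct <- sm$coefficients["x", ]
  slope <- unname(ct[1])
  flagged <- slope <= 0
  if (flagged) warning("non-positive flux-force slope; fit flagged")
  structure(list(L = slope / cE,
                 L_stderr = unname(ct[2]) / cE,
                 r_squared = sm$r.squared,
                 p_value_slope = unname(ct[4]),
                 n_points = nrow(d),
                 flagged = flagged,
                 intercept = if (intercept)
                   unname(stats::coef(fit)[1]) else 0),
            class = "flux_force_fit")
}

#' @export
print.flux_force_fit <- function(x, ...) {
  cat(sprintf(
    "<flux_force_fit> L = %.4g +/- %.2g 1/s (R2 = %.5f, n = %d)\n",
    x$L, x$L_stderr, x$r_squared, x$n_points))
  invisible(x)
}

#' Fit a separable (Noor) rate law to a trimmed trace
#'
#' Nonlinear least squares of rate against substrate molality for the
#' substrate-saturation form (`rmax`, `KS`) or the product-saturation form
#' (`Lambda`, `KP`), with `cSeq` and `cS0` held fixed at their known
#' values. Initial guesses are taken from the data (`rmax0 = 1.5 max r`,
#' `KS0 = median cS`; `Lambda0 = max r / cS0`, `KP0 = 0.2 cS0`) and the
#' optimiser is restarted from five deterministically jittered starts,
#' keeping the converged fit with the smallest residual sum of squares;
#' parameters are bounded below at zero.
#'
#' @param trace a trimmed `kinetic_trace` (non-flux-force trimming).
#' @param variant `"substrate"` or `"product"`.
#' @param eq the `equilibrium_state`.
#' @param cS0 initial substrate molality; defaults to the trace attribute.
#' @return object of class `noor_fit`: list with `params` (a
#'   [noor_substrate_params()] or [noor_product_params()]),
#'   `param_stderrs`, `r_squared`, `n_points`, `variant`.
#' @export
fit_noor <- function(trace, variant = c("substrate", "product"), eq,
                     cS0 = attr(trace, "cS0")) {
  variant <- match.arg(variant)
  stopifnot(inherits(trace, "kinetic_trace"),
            inherits(eq, "equilibrium_state"))
  keep <- trace$included & is.finite(trace$r) & trace$cS > 0
  if (sum(keep) < 8) stop("fewer than 8 included points; cannot fit")
  d <- data.frame(cS = trace$cS[keep], r = trace$r[keep])
  if (max(d$r) <= 0 || stats::sd(d$r) == 0) {
    stop("degenerate trace: rates carry no kinetic information")
  }
  cSeq <- eq$cSeq
  if (variant == "substrate") {
    form <- r ~ rmax * (cS / KS) / (1 + cS / KS) *
      (1 - cSeq * (cS0 - cS) / ((cS0 - cSeq) * cS))
    start0 <- c(rmax = 1.5 * max(d$r), KS = stats::median(d$cS))
  } else {
    form <- r ~ Lambda * cS / (1 + (cS0 - cS) / KP) *
      (1 - cSeq * (cS0 - cS) / ((cS0 - cSeq) * cS))
    start0 <- c(Lambda = max(d$r) / cS0, KP = 0.2 * cS0)
  }
  # deterministic multi-start: base guess plus fixed jitter factors
  jitters <- list(c(1, 1), c(0.3, 0.3), c(3, 3), c(0.3, 3), c(3, 0.3),
                  c(10, 1))
  best <- NULL
  for (j in jitters) {
    st <- start0 * j
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = d, start = as.list(st),
                        lower = c(1e-15, 1e-15),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    stop(sprintf(
      "nonlinear fit of the %s-saturation law failed to converge from any start",
      variant))
  }
  fit <- best$fit
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  r_squared <- 1 - best$rss / sum((d$r - mean(d$r))^2)
  params <- if (variant == "substrate") {
    noor_substrate_params(est[["rmax"]], est[["KS"]])
  } else {
    noor_product_params(est[["Lambda"]], est[["KP"]])
  }
  structure(list(params = params,
                 param_stderrs = se,
                 r_squared = r_squared,
                 n_points = nrow(d),
                 variant = variant),
            class = "noor_fit")
}

#' @export
print.noor_fit <- function(x, ...) {
  p <- unlist(x$params)
  cat(sprintf("<noor_fit> %s saturation: %s (R2 = %.5f, n = %d)\n",
              x$variant,
              paste(sprintf("%s = %.4g", names(p), p), collapse = ", "),
              x$r_squared, x$n_points))
  invisible(x)
}

#' Arrhenius regression of a kinetic coefficient
#'
#' Ordinary least squares of `ln(value)` on `1/T`; the activation energy
#' is `Ea = -slope * R` and the pre-exponential factor `A =
#' exp(intercept)`. The slope p-value is the two-sided t-test with
#' `n - 2` degrees of freedom.
#'
#' @param values positive kinetic coefficients (e.g. flux-force `L`).
#' @param temperatures matching temperatures, K (>= 2 distinct; >= 3
#'   recommended for a standard error).
#' @return object of class `arrhenius_fit`: list with `Ea` (J mol^-1),
#'   `A`, `Ea_stderr`, `r_squared`, `p_value_slope`, `n`.
#' @examples
#' fit_arrhenius(c(217.18, 358.80, 518.44),
#'               c(298.15, 305.15, 310.15))$Ea / 1e3  # ~55.4 kJ/mol
#' @export
fit_arrhenius <- function(values, temperatures) {
  if (length(values) != length(temperatures)) {
    stop("values and temperatures must have equal length")
  }
  if (any(values <= 0)) stop("all values must be > 0 (log is taken)")
  if (length(unique(temperatures)) < 2) {
    stop("need at least two distinct temperatures")
  }
  x <- 1 / temperatures
  y <- log(values)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  have_se <- length(y) > 2
  structure(list(
    Ea = -slope * .R_GAS,
    A = exp(unname(stats::coef(fit)[1])),
    Ea_stderr = if (have_se) sm$coefficients[2, 2] * .R_GAS else NA_real_,
    r_squared = sm$r.squared,
    p_value_slope = if (have_se) sm$coefficients[2, 4] else NA_real_,
    n = length(y)),
    class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf(
    "<arrhenius_fit> Ea = %.4g kJ/mol (se %.2g), A = %.4g 1/s, R2 = %.5f\n",
    x$Ea / 1e3, x$Ea_stderr / 1e3, x$A, x$r_squared))
  invisible(x)
}

#' Activation energy implied by a Q10-style rate ratio
#'
#' Closed form of the Arrhenius law for a rate that changes by
#' `rate_ratio` between `T1` and `T2`:
#' `Ea = R * ln(rate_ratio) * T1 * T2 / (T2 - T1)`.
#' With the classical rule of thumb that a 10 K rise doubles the rate
#' (`rate_ratio = 2`), this gives a quick plausibility estimate for
#' measured activation energies.
#'
#' @param T1,T2 temperatures, K (distinct).
#' @param rate_ratio rate ratio between `T2` and `T1` (> 0).
#' @return activation energy, J mol^-1.
#' @examples
#' q10_activation_energy(298.15, 308.15, 2) / 1e3  # ~52.9 kJ/mol
#' @export
q10_activation_energy <- function(T1, T2, rate_ratio) {
  if (T1 == T2) stop("T1 and T2 must differ")
  if (rate_ratio <= 0) stop("rate_ratio must be > 0")
  .R_GAS * log(rate_ratio) * T1 * T2 / (T2 - T1)
}
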