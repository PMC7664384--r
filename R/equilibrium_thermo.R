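#' Molar reaction enthalpy from total heat
#'
#' `dH = Q / ((cS0 - cSeq) * m)`: the integrated reaction heat divided by
#' the moles of substrate converted before equilibrium was reached.
#'
#' @param Q total reaction heat, J.
#' @param cS0 initial substrate molality, mol kg^-1.
#' @param cSeq equilibrium substrate molality, mol kg^-1.
#' @param m mass of the reaction solution, kg.
#' @return reaction enthalpy, J mol^-1.
#' @examples
#' eq <- equilibrium_concentrations(
#'   reaction_system("isomerization", cS0 = 4.8e-3, cE = 14.3e-9,
#'                   m = 2e-4, temperature = 310.15, Kc = 0.343))
#' reaction_enthalpy(7.86e-3, 4.8e-3, eq$cSeq, 2e-4) / 1e3  # kJ/mol
#' @export
reaction_enthalpy <- function(Q, cS0, cSeq, m) {
  stopifnot(is.numeric(Q), is.numeric(cS0), is.numeric(cSeq),
            is.numeric(m), m > 0)
  if (cS0 <= cSeq) {
    stop("no net conversion (cS0 <= cSeq): reaction enthalpy undefined")
  }
  Q / ((cS0 - cSeq) * m)
}

#' Concentration-based equilibrium ratio from the thermodynamic constant
#'
#' `Kc = Ka / Kgamma`, where `Ka` is the activity-based equilibrium
#' constant and `Kgamma` the ratio of activity coefficients of product and
#' substrate. With ideal-solution behaviour (`Kgamma = 1`), `Kc = Ka`.
#' Activity-coefficient prediction is out of scope here; `Kgamma` is a
#' user-supplied input.
#'
#' @param Ka thermodynamic equilibrium constant.
#' @param Kgamma activity-coefficient ratio (default 1, ideal solution).
#' @return `Kc`, same units as `Ka / Kgamma`.
#' @export
kc_from_ka <- function(Ka, Kgamma = 1) {
  if (any(Kgamma <= 0)) stop("Kgamma must be > 0")
  Ka / Kgamma
}

#' Van 't Hoff reaction enthalpy from Kc(T)
#'
#' Ordinary least squares of `ln Kc` against `1/T`; the reaction enthalpy
#' is `-slope * R`. At least two distinct temperatures are required; with
#' two points the fit is exact and no standard error is available.
#'
#' @param Kc equilibrium ratios (all > 0).
#' @param temperatures matching temperatures, K.
#' @return list with `dH` (J mol^-1), `dH_stderr`, `slope`, `intercept`,
#'   `r_squared`, `n`.
#' @examples
#' vant_hoff_enthalpy(c(0.285, 0.318, 0.343),
#'                    c(298.15, 305.15, 310.15))$dH / 1e3  # ~11.9 kJ/mol
#' @export
vant_hoff_enthalpy <- function(Kc, temperatures) {
  if (length(Kc) != length(temperatures)) {
    stop("Kc and temperatures must have equal length")
  }
  if (length(unique(temperatures)) < 2) {
    stop("need at least two distinct temperatures")
  }
  if (any(Kc <= 0)) stop("all Kc must be > 0")
  x <- 1 / temperatures
  y <- log(Kc)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  slope_se <- if (nrow(sm$coefficients) >= 2 && length(y) > 2) {
    sm$coefficients[2, 2]
  } else {
    NA_real_
  }
  list(dH = -slope * .R_GAS,
       dH_stderr = if (is.na(slope_se)) NA_real_ else slope_se * .R_GAS,
       slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       n = length(y))
}
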