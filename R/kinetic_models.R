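#' Thermodynamic driving force
#'
#' The dimensionless driving force of a reversible reaction,
#' `iota = 1 - exp(dG/RT)`, evaluated with activities approximated by
#' molalities:
#' `iota = 1 - (cSeq * cP) / (cS * cPeq)`.
#' It is 1 when no product is present, decays as the reaction proceeds and
#' is exactly 0 at equilibrium; negative values indicate a composition past
#' equilibrium (backward-proceeding reaction). The value is returned
#' unclipped.
#'
#' @param cS,cP substrate and product molality, mol kg^-1 (vectorized).
#' @param eq an `equilibrium_state` from [equilibrium_concentrations()].
#' @return numeric vector of driving-force values.
#' @export
driving_force <- function(cS, cP, eq) {
  stopifnot(inherits(eq, "equilibrium_state"))
  if (any(cS <= 0)) stop("driving force undefined for cS <= 0")
  if (eq$cPeq <= 0) stop("cPeq must be > 0")
  1 - (eq$cSeq * cP) / (cS * eq$cPeq)
}

#' Gibbs energy of reaction at a given composition
#'
#' `dG = R * T * ln(cSeq * cP / (cS * cPeq))` with activities approximated
#' by molalities. Satisfies `iota = 1 - exp(dG / (R * T))` exactly. For
#' `cP = 0` the Gibbs energy diverges and `-Inf` is returned as an explicit
#' sentinel rather than an error.
#'
#' @inheritParams driving_force
#' @param temperature temperature, K.
#' @return Gibbs energy of reaction, J mol^-1 (vectorized; `-Inf` at
#'   `cP = 0`).
#' @export
gibbs_energy <- function(cS, cP, eq, temperature) {
  stopifnot(inherits(eq, "equilibrium_state"), temperature > 0)
  if (any(cS <= 0)) stop("Gibbs energy undefined for cS <= 0")
  .R_GAS * temperature * log((eq$cSeq * cP) / (cS * eq$cPeq))
}

#' Flux-force rate-law parameters
#'
#' The one-parameter rate law of irreversible thermodynamics,
#' `r = L * cE * iota / (2 - iota)`, where `L` (s^-1) is the
#' phenomenological coefficient and `cE` the enzyme molality.
#'
#' @param L phenomenological coefficient, s^-1.
#' @param cE enzyme molality, mol kg^-1.
#' @export
flux_force_params <- function(L, cE) {
  stopifnot(is.numeric(L), L > 0, is.numeric(cE), cE > 0)
  structure(list(L = L, cE = cE), class = "flux_force_params")
}

#' Separable rate-law parameters, substrate saturation
#'
#' Two-parameter reduction of the separable (Noor) rate law when the enzyme
#' is saturated by the substrate only: `rmax` is the capacity `cE * kcat+`
#' and `KS` the Michaelis constant of the substrate.
#'
#' @param rmax maximum rate, mol kg^-1 s^-1.
#' @param KS Michaelis constant of the substrate, mol kg^-1.
#' @export
noor_substrate_params <- function(rmax, KS) {
  stopifnot(is.numeric(rmax), rmax > 0, is.numeric(KS), KS > 0)
  structure(list(rmax = rmax, KS = KS), class = "noor_substrate_params")
}

#' Separable rate-law parameters, product saturation
#'
#' Two-parameter reduction when the enzyme is saturated by the product:
#' `Lambda = cE * kcat+ / KS` (s^-1) lumps the capacity with the substrate
#' Michaelis constant (the two are not separately identifiable in this
#' regime), and `KP` is the Michaelis constant of the product.
#'
#' @param Lambda lumped kinetic coefficient, s^-1.
#' @param KP Michaelis constant of the product, mol kg^-1.
#' @export
noor_product_params <- function(Lambda, KP) {
  stopifnot(is.numeric(Lambda), Lambda > 0, is.numeric(KP), KP > 0)
  structure(list(Lambda = Lambda, KP = KP), class = "noor_product_params")
}

#' Flux-force reaction rate
#'
#' `r = L * cE * iota / (2 - iota)`. Zero exactly at equilibrium
#' (`iota = 0`) and strictly increasing in `iota` on `[0, 1]`.
#'
#' @param params a [flux_force_params()].
#' @param iota driving force (vectorized); must be `< 2`.
#' @return rate, mol kg^-1 s^-1.
#' @export
flux_force_rate <- function(params, iota) {
  stopifnot(inherits(params, "flux_force_params"))
  if (any(iota >= 2)) stop("flux-force rate undefined for iota >= 2")
  params$L * params$cE * iota / (2 - iota)
}

# Shared driving factor of the separable rate laws:
# 1 - cSeq*(cS0 - cS) / ((cS0 - cSeq)*cS), the molality form of iota under
# the mass balance cP = cS0 - cS. Vanishes at cS = cSeq.
.noor_driving <- function(cS, cS0, eq) {
  1 - eq$cSeq * (cS0 - cS) / ((cS0 - eq$cSeq) * cS)
}

#' Separable rate law with substrate saturation
#'
#' `r = rmax * (cS/KS) / (1 + cS/KS) *
#'   (1 - cSeq * (cS0 - cS) / ((cS0 - cSeq) * cS))`
#'
#' The first factor is the enzyme saturation by the substrate, the second
#' the thermodynamic driving force under the mass balance `cP = cS0 - cS`.
#' The rate is exactly zero at the equilibrium composition.
#'
#' @param params a [noor_substrate_params()].
#' @param cS substrate molality, mol kg^-1 (vectorized).
#' @param cS0 initial substrate molality, mol kg^-1.
#' @param eq an `equilibrium_state`.
#' @return rate, mol kg^-1 s^-1.
#' @export
noor_rate_substrate <- function(params, cS, cS0, eq) {
  stopifnot(inherits(params, "noor_substrate_params"),
            inherits(eq, "equilibrium_state"))
  if (any(cS <= 0)) stop("rate undefined for cS <= 0")
  sat <- (cS / params$KS) / (1 + cS / params$KS)
  params$rmax * sat * .noor_driving(cS, cS0, eq)
}

#' Separable rate law with product saturation
#'
#' `r = Lambda * cS / (1 + (cS0 - cS)/KP) *
#'   (1 - cSeq * (cS0 - cS) / ((cS0 - cSeq) * cS))`
#'
#' Product accumulation (`cP = cS0 - cS`) inhibits the enzyme through the
#' denominator; with no product present the rate is first order in `cS`.
#'
#' @param params a [noor_product_params()].
#' @inheritParams noor_rate_substrate
#' @return rate, mol kg^-1 s^-1.
#' @export
noor_rate_product <- function(params, cS, cS0, eq) {
  stopifnot(inherits(params, "noor_product_params"),
            inherits(eq, "equilibrium_state"))
  if (any(cS <= 0)) stop("rate undefined for cS <= 0")
  params$Lambda * cS / (1 + (cS0 - cS) / params$KP) *
    .noor_driving(cS, cS0, eq)
}

#' Separable rate law with double saturation
#'
#' Full form with both substrate and product in the saturation denominator:
#' `r = rmax * (cS/KS) / (1 + cS/KS + (cS0 - cS)/KP) * driving`. Provided
#' for completeness; the single-saturation reductions are the forms fitted
#' by default.
#'
#' @param rmax capacity, mol kg^-1 s^-1.
#' @param KS,KP Michaelis constants, mol kg^-1.
#' @inheritParams noor_rate_substrate
#' @return rate, mol kg^-1 s^-1.
#' @export
noor_rate_double <- function(rmax, KS, KP, cS, cS0, eq) {
  stopifnot(rmax > 0, KS > 0, KP > 0, inherits(eq, "equilibrium_state"))
  if (any(cS <= 0)) stop("rate undefined for cS <= 0")
  sat <- (cS / KS) / (1 + cS / KS + (cS0 - cS) / KP)
  rmax * sat * .noor_driving(cS, cS0, eq)
}

#' Irreversible Michaelis-Menten rate (comparison curve)
#'
#' `r = rmax * cS / (KS + cS)`; ignores the backward reaction, so it does
#' not vanish at equilibrium. Utility for plotting against the
#' equilibrium-aware laws, not a fitted model.
#'
#' @param rmax maximum rate, mol kg^-1 s^-1.
#' @param KS Michaelis constant, mol kg^-1.
#' @param cS substrate molality, mol kg^-1 (vectorized).
#' @export
mm_irreversible_rate <- function(rmax, KS, cS) {
  stopifnot(rmax > 0, KS > 0)
  rmax * cS / (KS + cS)
}
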