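#' @keywords internal
#' @noRd
.R_GAS <- 8.314  # universal gas constant, J mol^-1 K^-1

#' Molality of pure water
#'
#' Constant water molality (1000 g / 18.015 g mol^-1, rounded to the value
#' used throughout the analysis) assumed for dehydration-type reactions,
#' where water appears in the equilibrium ratio but is never depleted
#' appreciably by the reaction.
#' @export
WATER_MOLALITY <- 55.51  # mol kg^-1

#' Define a reversible enzyme reaction experiment
#'
#' Bundles the chemistry and the experimental context of a single-injection
#' calorimetric experiment: the stoichiometry class, initial substrate and
#' enzyme molalities in the cell, the solution mass, the temperature and the
#' concentration-based equilibrium ratio `Kc`.
#'
#' Two stoichiometry kinds are supported. `"isomerization"` is S = P
#' measured with the substrate on the numerator of `Kc` (the phosphoglucose
#' isomerase reaction measured as F6P -> G6P, where
#' `Kc = cSeq / cPeq`). `"dehydration"` is S = P + H2O measured backward
#' (the enolase reaction measured as PEP -> 2PG, where
#' `Kc = cSeq * cH2O / cPeq` and carries units of mol kg^-1). Water is held
#' at a constant molality because it is in vast excess.
#'
#' @param kind `"isomerization"` or `"dehydration"`.
#' @param cS0 initial substrate molality in the cell, mol kg^-1.
#' @param cE enzyme molality in the cell, mol kg^-1.
#' @param m mass of the reaction solution in the cell, kg.
#' @param temperature temperature, K.
#' @param Kc concentration-based equilibrium ratio (dimensionless for
#'   isomerization; mol kg^-1 for dehydration).
#' @param water_molality molality of water, mol kg^-1 (dehydration only).
#' @param substrate,product species names; defaulted per `kind`.
#' @return An object of class `reaction_system`.
#' @examples
#' pgi <- reaction_system("isomerization", cS0 = 4.8e-3, cE = 14.3e-9,
#'                        m = 2.0e-4, temperature = 310.15, Kc = 0.343)
#' equilibrium_concentrations(pgi)
#' @export
reaction_system <- function(kind = c("isomerization", "dehydration"),
                            cS0, cE, m, temperature, Kc,
                            water_molality = WATER_MOLALITY,
                            substrate = NULL, product = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(cS0), length(cS0) == 1L, cS0 > 0,
            is.numeric(cE), length(cE) == 1L, cE > 0,
            is.numeric(m), length(m) == 1L, m > 0,
            is.numeric(temperature), length(temperature) == 1L,
            temperature > 0,
            is.numeric(Kc), length(Kc) == 1L)
  if (Kc <= 0) stop("Kc must be > 0")
  if (kind == "dehydration" &&
      (!is.numeric(water_molality) || water_molality <= 0)) {
    stop("water_molality must be set and > 0 for dehydration reactions")
  }
  if (is.null(substrate)) {
    substrate <- if (kind == "isomerization") "F6P" else "PEP"
  }
  if (is.null(product)) {
    product <- if (kind == "isomerization") "G6P" else "2PG"
  }
  stoich <- if (kind == "isomerization") {
    stats::setNames(c(-1, 1), c(substrate, product))
  } else {
    stats::setNames(c(-1, 1, 1), c(substrate, product, "H2O"))
  }
  structure(
    list(kind = kind, cS0 = cS0, cE = cE, m = m,
         temperature = temperature, Kc = Kc,
         water_molality = if (kind == "dehydration") water_molality else NA_real_,
         substrate = substrate, product = product, stoich = stoich),
    class = "reaction_system")
}

#' @export
print.reaction_system <- function(x, ...) {
  cat(sprintf("<reaction_system> %s: %s -> %s\n",
              x$kind, x$substrate, x$product))
  cat(sprintf("  cS0 = %.4g mol/kg, cE = %.4g mol/kg, m = %.4g kg\n",
              x$cS0, x$cE, x$m))
  cat(sprintf("  T = %.2f K, Kc = %.4g%s\n", x$temperature, x$Kc,
              if (x$kind == "dehydration") " mol/kg" else ""))
  invisible(x)
}

#' Equilibrium composition from the equilibrium ratio
#'
#' Solves the equilibrium molalities of the measured substrate and product
#' from `Kc` and the mass balance `cSeq + cPeq = cS0` (water excluded).
#'
#' For an isomerization measured as S -> P with `Kc = cSeq / cPeq`,
#' `cSeq = cS0 * Kc / (1 + Kc)`. For a dehydration measured as
#' S -> P + H2O with `Kc = cSeq * cH2O / cPeq` and water constant,
#' `cPeq = cH2O * cS0 / (cH2O + Kc)`.
#'
#' @param rs a [reaction_system()].
#' @return An object of class `equilibrium_state` with fields `cSeq`
#'   and `cPeq` (mol kg^-1).
#' @export
equilibrium_concentrations <- function(rs) {
  stopifnot(inherits(rs, "reaction_system"))
  if (rs$Kc <= 0) stop("Kc must be > 0")
  if (rs$kind == "isomerization") {
    cSeq <- rs$cS0 * rs$Kc / (1 + rs$Kc)
    cPeq <- rs$cS0 - cSeq
  } else {
    cPeq <- rs$water_molality * rs$cS0 / (rs$water_molality + rs$Kc)
    cSeq <- rs$cS0 - cPeq
  }
  structure(list(cSeq = cSeq, cPeq = cPeq), class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium_state> cSeq = %.6g, cPeq = %.6g mol/kg\n",
              x$cSeq, x$cPeq))
  invisible(x)
}
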