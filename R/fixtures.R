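#' Reference measurement tables for the two glycolytic reactions
#'
#' Loads the packaged reference values for the phosphoglucose isomerase
#' (PGI, measured as F6P -> G6P) and enolase (measured as PEP -> 2PG)
#' reactions: integrated heats, equilibrium ratios and reaction enthalpies
#' at 298.15 / 305.15 / 310.15 K (`thermo`), the separable rate-law
#' parameters (`noor`), the flux-force coefficients (`flux_force`), and
#' the PGI reaction enthalpy in three buffer systems (`buffers`). Each
#' value keeps its reported standard deviation where one was given.
#'
#' Unit conventions in the tables: `Q_mJ` in mJ; `Kc` dimensionless (PGI)
#' or mol kg^-1 (enolase); `rmax` in umol kg^-1 s^-1; Michaelis constants
#' in mmol kg^-1; `Lambda` in 1e-3 s^-1; `L` in s^-1; enthalpies in
#' kJ mol^-1.
#'
#' @return named list of data frames: `thermo`, `noor`, `flux_force`,
#'   `buffers`.
#' @examples
#' fx <- load_fixture_tables()
#' subset(fx$flux_force, reaction == "pgi")
#' @export
load_fixture_tables <- function() {
  read_one <- function(name) {
    utils::read.csv(system.file("extdata", name, package = "thermokin",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
  list(thermo = read_one("thermo_equilibrium.csv"),
       noor = read_one("noor_parameters.csv"),
       flux_force = read_one("flux_force_L.csv"),
       buffers = read_one("buffer_enthalpies.csv"))
}

#' Standard reaction systems for the two worked examples
#'
#' Convenience constructors for the cell compositions of the two
#' single-injection experiments: 14.3 nmol kg^-1 PGI with 4.8 mmol kg^-1
#' F6P, and 2 umol kg^-1 enolase with 74.8 mmol kg^-1 PEP, with the
#' equilibrium ratio looked up from the packaged tables at the requested
#' temperature. The cell solution mass defaults to 2.0e-4 kg (nominal
#' 200 uL cell).
#'
#' @param temperature one of 298.15, 305.15, 310.15 K.
#' @param m solution mass in the cell, kg.
#' @return a [reaction_system()].
#' @export
pgi_system <- function(temperature = 310.15, m = 2.0e-4) {
  Kc <- .lookup_kc("pgi", temperature)
  reaction_system("isomerization", cS0 = 4.8e-3, cE = 14.3e-9, m = m,
                  temperature = temperature, Kc = Kc)
}

#' @rdname pgi_system
#' @export
enolase_system <- function(temperature = 310.15, m = 2.0e-4) {
  Kc <- .lookup_kc("enolase", temperature)
  reaction_system("dehydration", cS0 = 74.8e-3, cE = 2e-6, m = m,
                  temperature = temperature, Kc = Kc)
}

.lookup_kc <- function(reaction, temperature) {
  tab <- load_fixture_tables()$thermo
  row <- tab[tab$reaction == reaction &
               abs(tab$temperature_K - temperature) < 1e-6, ]
  if (nrow(row) != 1) {
    stop(sprintf("no tabulated Kc for %s at %.2f K", reaction, temperature))
  }
  row$Kc
}
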