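#!/usr/bin/env Rscript
# Emulate the full measurement campaign for the PGI reaction: triplicate
# single-injection experiments at three temperatures, each processed and
# fitted with the flux-force model, then an Arrhenius regression over the
# replicate-mean coefficients. Everything is driven by run_pipeline().

suppressPackageStartupMessages(library(thermokin))

config <- list(
  seed = 20260927,
  outdir = "results/pipeline",
  reactions = list(list(
    name = "pgi", kind = "isomerization", model = "flux_force",
    cS0_mol_per_kg = 4.8e-3, cE_mol_per_kg = 14.3e-9, m_kg = 2.0e-4,
    dH_J_per_mol = 11.1e3, replicates = 3,
    simulate = list(duration_s = 5000, dt_s = 1, tau_s = 10,
                    noise_sd_W = 2e-8),
    temperatures = list(
      list(T_K = 298.15, Kc = 0.285, L_per_s = 217.18),
      list(T_K = 305.15, Kc = 0.318, L_per_s = 358.80),
      list(T_K = 310.15, Kc = 0.343, L_per_s = 518.44)))))

res <- run_pipeline(config)

s <- res$summary$reactions$pgi
cat("\nReplicate-mean flux-force coefficients:\n")
for (row in s$per_temperature) {
  cat(sprintf("  T = %.2f K: L = %.2f +/- %.2f 1/s (n = %d)\n",
              row$T_K, row$mean, row$sd, row$replicates))
}
cat(sprintf("\nArrhenius over the means: Ea = %.1f +/- %.1f kJ/mol (R2 = %.4f, p = %.3g)\n",
            s$arrhenius$Ea_J_per_mol / 1e3,
            s$arrhenius$Ea_stderr_J_per_mol / 1e3,
            s$arrhenius$r_squared, s$arrhenius$p_value_slope))
cat("Outputs (per-trace CSVs, per-fit JSONs, summary.json) are under\n")
cat("results/pipeline/. Rerunning with the same seed reproduces them\n")
cat("byte-for-byte.\n")
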