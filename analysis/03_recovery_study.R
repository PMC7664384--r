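#!/usr/bin/env Rscript
# Ground-truth recovery study: simulate single-injection thermograms for
# the three rate laws at the tabulated 310.15 K parameters, run the full
# processing chain (power -> rate/concentration -> trim -> fit), and
# report relative recovery errors for an ideal instrument and for a
# realistic one (first-order response tau = 10 s, 0.02 uW noise).

suppressPackageStartupMessages(library(thermokin))
dir.create("results", showWarnings = FALSE)

pgi <- pgi_system(310.15)
eno <- enolase_system(310.15)
truth <- list(L = 518.44, rmax = 13.21e-6, KS = 3.26e-3,
              Lambda = 5.7e-4, KP = 16.5e-3)
noisy_seeds <- c(101, 202, 303)

one_run <- function(model, rs, params, dH, duration, dt, tau, noise, seed) {
  eq <- equilibrium_concentrations(rs)
  cfg <- simulation_config(model, params, rs, duration = duration,
                           dt = dt, tau_instrument = tau,
                           noise_sd = noise, seed = seed)
  tr <- simulate_progress(cfg)
  tg <- simulate_thermogram(tr, rs, dH, cfg)
  trace <- to_concentration_trace(tg, dH, rs$m, rs$cS0)
  if (model == "flux_force") {
    fit <- fit_flux_force(apply_trim_rules(trace, eq, TRUE), rs$cE)
    est <- c(L = fit$L)
  } else {
    variant <- if (model == "noor_substrate") "substrate" else "product"
    fit <- fit_noor(apply_trim_rules(trace, eq), variant, eq)
    est <- unlist(fit$params)
  }
  data.frame(model = model, condition = if (noise > 0) "noisy" else "ideal",
             seed = if (is.null(seed)) NA_integer_ else seed,
             parameter = names(est), estimate = unname(est),
             truth = unname(unlist(truth[names(est)])),
             rel_error = abs(unname(est) -
                               unname(unlist(truth[names(est)]))) /
               unname(unlist(truth[names(est)])),
             r_squared = fit$r_squared)
}

designs <- list(
  list(model = "flux_force", rs = pgi,
       params = flux_force_params(truth$L, pgi$cE),
       dH = 11.1e3, duration = 3600, dt = 1),
  list(model = "noor_substrate", rs = pgi,
       params = noor_substrate_params(truth$rmax, truth$KS),
       dH = 11.1e3, duration = 3600, dt = 1),
  list(model = "noor_product", rs = eno,
       params = noor_product_params(truth$Lambda, truth$KP),
       dH = 2.4e3, duration = 6000, dt = 2))

rows <- list()
for (d in designs) {
  rows[[length(rows) + 1]] <-
    with(d, one_run(model, rs, params, dH, duration, dt,
                    tau = 0, noise = 0, seed = NULL))
  for (s in noisy_seeds) {
    rows[[length(rows) + 1]] <-
      with(d, one_run(model, rs, params, dH, duration, dt,
                      tau = 10, noise = 2e-8, seed = s))
  }
}
out <- do.call(rbind, rows)
write.csv(out, "results/recovery.csv", row.names = FALSE)

cat("Parameter recovery through the full processing chain:\n")
print(out, digits = 3, row.names = FALSE)
cat(sprintf("\nWorst-case relative error, ideal instrument: %.2g\n",
            max(out$rel_error[out$condition == "ideal"])))
cat(sprintf("Worst-case relative error, tau = 10 s + 0.02 uW noise: %.2g\n",
            max(out$rel_error[out$condition == "noisy"])))
cat("The trim rules (drop everything up to the rate maximum; in\n")
cat("flux-force mode also every point with iota/(2-iota) > 0.6) are what\n")
cat("keeps the instrument-distorted head of the record out of the fits.\n")
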