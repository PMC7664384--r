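# Standard experimental designs used across the tests: the PGI cell
# (4.8 mmol/kg F6P, 14.3 nmol/kg enzyme) and the enolase cell
# (74.8 mmol/kg PEP, 2 umol/kg enzyme), both at 310.15 K with the
# tabulated Kc, nominal 2.0e-4 kg cell mass.

pgi_truth <- list(
  L = 518.44,                    # 1/s
  rmax = 13.21e-6,               # mol/kg/s
  KS = 3.26e-3,                  # mol/kg
  dH = 11.1e3)                   # J/mol

enolase_truth <- list(
  L = 20.37,                     # 1/s
  Lambda = 5.7e-4,               # 1/s (0.57 in units of 1e-3/s)
  KP = 16.5e-3,                  # mol/kg
  dH = 2.4e3)                    # J/mol

# simulate -> thermogram -> concentration trace for a standard design;
# returns list(trace_true, tg, trace, eq, rs, cfg)
run_chain <- function(model_kind, params, rs,
                      duration, dt,
                      tau = 0, noise_sd = 0, seed = NULL,
                      delta_h) {
  eq <- equilibrium_concentrations(rs)
  cfg <- simulation_config(model_kind, params, rs,
                           duration = duration, dt = dt,
                           tau_instrument = tau, noise_sd = noise_sd,
                           seed = seed)
  trace_true <- simulate_progress(cfg)
  tg <- simulate_thermogram(trace_true, rs, delta_h, cfg)
  trace <- to_concentration_trace(tg, delta_h, rs$m, rs$cS0)
  list(trace_true = trace_true, tg = tg, trace = trace,
       eq = eq, rs = rs, cfg = cfg)
}

pgi_chain <- function(model_kind = "flux_force",
                      params = flux_force_params(pgi_truth$L, 14.3e-9),
                      tau = 0, noise_sd = 0, seed = NULL,
                      duration = 3600, dt = 1) {
  run_chain(model_kind, params, pgi_system(310.15),
            duration = duration, dt = dt, tau = tau,
            noise_sd = noise_sd, seed = seed, delta_h = pgi_truth$dH)
}

enolase_chain <- function(model_kind = "noor_product",
                          params = noor_product_params(enolase_truth$Lambda,
                                                       enolase_truth$KP),
                          tau = 0, noise_sd = 0, seed = NULL,
                          duration = 6000, dt = 2) {
  run_chain(model_kind, params, enolase_system(310.15),
            duration = duration, dt = dt, tau = tau,
            noise_sd = noise_sd, seed = seed, delta_h = enolase_truth$dH)
}
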