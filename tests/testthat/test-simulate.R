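# Synthetic thermogram generator: ODE progress curves, the instrument
# model, determinism, and fixture tables.

test_that("simulated progress decays monotonically to equilibrium", {
  for (ch in list(pgi_chain(), enolase_chain())) {
    tr <- ch$trace_true
    expect_true(all(diff(tr$cS) <= 0))
    expect_equal(utils::tail(tr$cS, 1), ch$eq$cSeq, tolerance = 1e-4)
    expect_true(all(tr$r >= 0))
    expect_true(all(tr$iota >= 0 & tr$iota <= 1))
  }
})

test_that("initial flux-force rate equals L*cE at full driving force", {
  ch <- pgi_chain()
  expect_equal(ch$trace_true$r[1], 518.44 * 14.3e-9, tolerance = 1e-10)
})

test_that("parameters implying a non-positive initial rate are rejected", {
  rs <- pgi_system(310.15)
  # a corrupted parameter object (negative coefficient) slips past the
  # constructor checks; the simulator must still reject it
  bad <- structure(list(L = -518.44, cE = rs$cE),
                   class = "flux_force_params")
  cfg <- simulation_config("flux_force", bad, rs, duration = 100, dt = 1,
                           tau_instrument = 0, noise_sd = 0)
  expect_error(simulate_progress(cfg), "non-positive initial rate")
})

test_that("identity instrument reproduces the ideal power exactly", {
  ch <- pgi_chain(tau = 0, noise_sd = 0)
  expect_equal(ch$tg$power,
               ch$trace_true$r * pgi_truth$dH * ch$rs$m)
})

test_that("integrated heat matches the conversion closed form", {
  # (cS0 - cSeq) * m * dH = 7.93 mJ for the PGI design
  ch <- pgi_chain()
  target <- (ch$rs$cS0 - ch$eq$cSeq) * ch$rs$m * pgi_truth$dH
  expect_equal(target, 7.93e-3, tolerance = 1e-3)
  expect_equal(integrate_heat(ch$tg), target, tolerance = 1e-3)
})

test_that("the first-order instrument response conserves heat", {
  ch0 <- pgi_chain(tau = 0)
  ch10 <- pgi_chain(tau = 10)
  Q0 <- integrate_heat(ch0$tg)
  Q10 <- integrate_heat(ch10$tg)
  expect_lt(abs(Q10 - Q0) / Q0, 1e-3)
  # the filter genuinely changes the waveform
  expect_gt(max(abs(ch10$tg$power - ch0$tg$power)), 1e-7)
  # warning when the sampling is too coarse for the time constant
  expect_warning(pgi_chain(tau = 1, duration = 300), "coarse")
})

test_that("dilution pulse adds exactly its nominal heat", {
  rs <- pgi_system(310.15)
  cfg <- simulation_config("flux_force", flux_force_params(518.44, rs$cE),
                           rs, duration = 3600, dt = 1,
                           tau_instrument = 0, noise_sd = 0,
                           dilution_heat = 1e-3, dilution_width = 5,
                           injection_time = 60)
  tr <- simulate_progress(cfg)
  tg <- simulate_thermogram(tr, rs, pgi_truth$dH, cfg)
  tg0 <- pgi_chain()$tg
  expect_equal(integrate_heat(tg) - integrate_heat(tg0), 1e-3,
               tolerance = 1e-3)
})

test_that("a fixed seed reproduces the noisy thermogram bit-identically", {
  a <- pgi_chain(tau = 10, noise_sd = 2e-8, seed = 77, duration = 600)
  b <- pgi_chain(tau = 10, noise_sd = 2e-8, seed = 77, duration = 600)
  expect_identical(a$tg$power, b$tg$power)
  c <- pgi_chain(tau = 10, noise_sd = 2e-8, seed = 78, duration = 600)
  expect_false(identical(a$tg$power, c$tg$power))
})

test_that("ideal-instrument round trip recovers the ODE solution", {
  ch <- pgi_chain(duration = 1200, dt = 0.2)
  expect_lt(max(abs(ch$trace$cS - ch$trace_true$cS)), 1e-9)
  expect_equal(ch$trace$r, ch$trace_true$r)
})

test_that("fixture tables carry the tabulated reference values", {
  fx <- load_fixture_tables()
  expect_named(fx, c("thermo", "noor", "flux_force", "buffers"))
  # flux-force coefficient, PGI at 298.15 K
  expect_equal(fx$flux_force$L_per_s[fx$flux_force$reaction == "pgi" &
                 fx$flux_force$temperature_K == 298.15], 217.18)
  # equilibrium ratio, enolase at 298.15 K (mol/kg)
  expect_equal(fx$thermo$Kc[fx$thermo$reaction == "enolase" &
                 fx$thermo$temperature_K == 298.15], 239.4)
  # product Michaelis constant, enolase at 310.15 K (mmol/kg)
  k2pg <- subset(fx$noor, reaction == "enolase" &
                   temperature_K == 310.15 & parameter == "K_2PG")
  expect_equal(k2pg$value, 16.5)
  expect_equal(k2pg$sd, 0.48)
  # every tabulated value retains an uncertainty column
  expect_true(all(c("Q_sd_mJ", "dH_sd_kJ_per_mol") %in% names(fx$thermo)))
  expect_true(all(fx$buffers$dH_sd_kJ_per_mol > 0))
})
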