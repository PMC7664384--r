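# Thermogram construction, reference subtraction, heat integration and
# the power-to-concentration transform.

make_tg <- function(time, power, temperature = 310.15) {
  thermogram(time, power, temperature = temperature)
}

test_that("thermogram construction validates its inputs", {
  expect_s3_class(make_tg(0:10, rep(1e-6, 11)), "thermogram")
  expect_error(make_tg(c(0, 1, 1), rep(0, 3)), "increasing")
  expect_error(make_tg(0:1, rep(0, 2)), "length")
  expect_error(make_tg(0:3, c(0, NA, 0, 0)), "finite")
})

test_that("reference subtraction is exact for aligned and shifted grids", {
  raw <- make_tg(0:100, rep(10e-6, 101))
  zero <- make_tg(0:100, rep(0, 101))
  expect_equal(subtract_reference(raw, zero)$power, raw$power)
  expect_equal(subtract_reference(raw, raw)$power, rep(0, 101))
  # constant reference on a half-step-shifted grid interpolates exactly
  ref <- make_tg(seq(0.5, 100.5, by = 1), rep(4e-6, 101))
  expect_equal(subtract_reference(raw, ref)$power, rep(6e-6, 101))
  # two references subtract additively
  expect_equal(subtract_reference(raw, list(ref, ref))$power,
               rep(2e-6, 101))
})

test_that("reference subtraction rejects incompatible inputs", {
  raw <- make_tg(0:100, rep(10e-6, 101))
  warm <- make_tg(0:100, rep(4e-6, 101), temperature = 310.35)
  expect_error(subtract_reference(raw, warm), "0.1 K")
  late <- make_tg(200:300, rep(4e-6, 101))
  expect_error(subtract_reference(raw, late), "overlap")
})

test_that("heat integration is exact on rectangles and additive", {
  tg <- make_tg(0:1000, rep(1e-6, 1001))
  expect_equal(integrate_heat(tg), 1.0e-3)
  expect_equal(integrate_heat(make_tg(0:1000, rep(0, 1001))), 0)
  # additivity over adjacent windows, including non-grid edges
  tg2 <- make_tg(0:1000, 1e-6 * sin(0:1000 / 100)^2)
  expect_equal(integrate_heat(tg2, 0, 333.5) +
                 integrate_heat(tg2, 333.5, 1000),
               integrate_heat(tg2))
  expect_error(integrate_heat(tg, -5, 100), "window")
})

test_that("power-to-concentration transform matches hand arithmetic", {
  # constant 2.22e-6 W with dH = 11.1 kJ/mol, m = 2e-4 kg:
  # r = 1e-6 mol/kg/s and cS drops by 1e-5 mol/kg over 10 s
  tg <- make_tg(0:100, rep(2.22e-6, 101))
  tr <- to_concentration_trace(tg, 11.1e3, 2e-4, cS0 = 4.8e-3)
  expect_equal(tr$r, rep(1.0e-6, 101))
  expect_equal(tr$cS[tr$time == 10], 4.8e-3 - 1.0e-5)
  # zero power: nothing happens
  tr0 <- to_concentration_trace(make_tg(0:100, rep(0, 101)),
                                11.1e3, 2e-4, cS0 = 4.8e-3)
  expect_equal(tr0$cS, rep(4.8e-3, 101))
  expect_equal(tr0$r, rep(0, 101))
})

test_that("transform errors when the implied substrate goes negative", {
  tg <- make_tg(0:1000, rep(2.22e-6, 1001))  # drains 1e-3 mol/kg
  expect_error(to_concentration_trace(tg, 11.1e3, 2e-4, cS0 = 5e-4),
               "negative at t")
})

test_that("cS is non-increasing whenever power is non-negative", {
  set.seed(11)
  p <- abs(rnorm(500, 1e-6, 5e-7))
  tr <- to_concentration_trace(make_tg(0:499, p), 11.1e3, 2e-4, 4.8e-3)
  expect_true(all(diff(tr$cS) <= 0))
})

test_that("trim rules drop the pre-maximum head and far-from-equilibrium tail", {
  eq <- equilibrium_concentrations(pgi_system(310.15))
  ch <- pgi_chain()  # noise-free flux-force chain, max r at first sample
  trimmed <- apply_trim_rules(ch$trace, eq, flux_force_mode = FALSE)
  expect_false(trimmed$included[1])
  expect_true(all(trimmed$included[-1]))
  # flux-force mode: additionally every point with iota > 0.75 is dropped
  ff <- apply_trim_rules(ch$trace, eq, flux_force_mode = TRUE)
  expect_true(all(ff$iota[ff$included] <= 0.75 + 1e-12))
  expect_true(all(!ff$included[ff$iota / (2 - ff$iota) > 0.6]))
  # near-equilibrium samples past the head are never trimmed
  late <- setdiff(which(ff$iota < 0.5), 1L)
  expect_true(all(ff$included[late]))
  # the extra rule only removes points relative to plain trimming
  expect_false(any(ff$included & !trimmed$included))
})

test_that("trimming an unfittable trace errors", {
  eq <- equilibrium_concentrations(pgi_system(310.15))
  tr <- kinetic_trace(0:5, seq(4.8e-3, 4.0e-3, length.out = 6),
                      r = c(1, 2, 3, 4, 5, 6) * 1e-6, cS0 = 4.8e-3)
  # maximum r at the last point: nothing remains
  expect_error(apply_trim_rules(tr, eq), "fewer than 5")
})

test_that("thermogram CSV round-trips through write/read", {
  ch <- pgi_chain(duration = 100, dt = 1)
  path <- file.path(tempdir(), "tg.csv")
  write_thermogram(ch$tg, path)
  back <- read_thermogram(path)
  expect_equal(back$time, ch$tg$time)
  expect_equal(back$power, ch$tg$power)
  expect_equal(attr(back, "temperature"), 310.15)
  unlink(c(path, paste0(path, ".json")))
})
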