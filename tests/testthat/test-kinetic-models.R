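# Pure rate-law layer: driving force, Gibbs energy and the three
# equilibrium-aware rate laws.

pgi_eq <- equilibrium_concentrations(pgi_system(310.15))
eno_eq <- equilibrium_concentrations(enolase_system(310.15))

test_that("driving force hits its anchor points and the worked value", {
  # equilibrium composition -> 0; pure substrate -> 1
  expect_equal(driving_force(pgi_eq$cSeq, pgi_eq$cPeq, pgi_eq), 0)
  expect_equal(driving_force(3.3e-3, 0, pgi_eq), 1)
  # worked PGI state partway to equilibrium
  expect_equal(driving_force(3.0e-3, 1.8e-3, pgi_eq), 0.79420,
               tolerance = 1e-4)
  expect_error(driving_force(0, 1e-3, pgi_eq), "cS")
})

test_that("Gibbs energy is consistent with the driving force", {
  expect_equal(gibbs_energy(pgi_eq$cSeq, pgi_eq$cPeq, pgi_eq, 310.15), 0)
  expect_equal(gibbs_energy(3.0e-3, 1.8e-3, pgi_eq, 310.15), -4076.4,
               tolerance = 1e-4)
  # cP = 0 diverges to -Inf as a sentinel, not an error
  expect_identical(gibbs_energy(3e-3, 0, pgi_eq, 310.15), -Inf)
  # identity iota = 1 - exp(dG/RT) on random valid compositions
  set.seed(42)
  for (i in 1:50) {
    cS <- runif(1, pgi_eq$cSeq, 4.8e-3)
    cP <- 4.8e-3 - cS
    dG <- gibbs_energy(cS, cP, pgi_eq, 310.15)
    expect_equal(driving_force(cS, cP, pgi_eq),
                 1 - exp(dG / (8.314 * 310.15)), tolerance = 1e-12)
  }
})

test_that("flux-force rate matches hand-evaluated values and is monotone", {
  p <- flux_force_params(518.44, 14.3e-9)
  expect_equal(flux_force_rate(p, 0), 0)
  expect_equal(flux_force_rate(p, 1), 7.414e-6, tolerance = 1e-4)
  # the trim-threshold point: iota = 0.75 maps to x = 0.6
  expect_equal(flux_force_rate(p, 0.75) / (p$L * p$cE), 0.6)
  iotas <- seq(0, 1, by = 0.05)
  expect_true(all(diff(flux_force_rate(p, iotas)) > 0))
  expect_error(flux_force_rate(p, 2), "iota")
})

test_that("flux-force ratio reproduces the (1-e^x)/(1+e^x) algebra", {
  # iota/(2-iota) must equal (1 - e^x)/(1 + e^x) for x = dG/RT < 0
  set.seed(7)
  x <- -rexp(100)
  iota <- 1 - exp(x)
  expect_equal(iota / (2 - iota), (1 - exp(x)) / (1 + exp(x)),
               tolerance = 1e-14)
})

test_that("substrate-saturation law matches the worked PGI value", {
  p <- noor_substrate_params(13.21e-6, 3.26e-3)
  expect_equal(noor_rate_substrate(p, pgi_eq$cSeq, 4.8e-3, pgi_eq), 0)
  expect_equal(noor_rate_substrate(p, 3.0e-3, 4.8e-3, pgi_eq), 5.03e-6,
               tolerance = 1e-3)
  # no product: driving term is 1, plain saturation remains
  expect_equal(noor_rate_substrate(p, 4.8e-3, 4.8e-3, pgi_eq),
               13.21e-6 * (4.8 / 3.26) / (1 + 4.8 / 3.26))
  expect_error(noor_rate_substrate(p, 0, 4.8e-3, pgi_eq), "cS")
})

test_that("product-saturation law matches the worked enolase value", {
  p <- noor_product_params(5.7e-4, 16.5e-3)
  expect_equal(noor_rate_product(p, eno_eq$cSeq, 74.8e-3, eno_eq), 0)
  expect_equal(noor_rate_product(p, 70e-3, 74.8e-3, eno_eq), 2.13e-5,
               tolerance = 1e-3)
  # no product accumulated: first order in cS
  expect_equal(noor_rate_product(p, 74.8e-3, 74.8e-3, eno_eq),
               5.7e-4 * 74.8e-3)
})

test_that("all rate laws vanish exactly at the equilibrium composition", {
  expect_identical(
    flux_force_rate(flux_force_params(100, 1e-8),
                    driving_force(pgi_eq$cSeq, pgi_eq$cPeq, pgi_eq)), 0)
  expect_identical(
    noor_rate_substrate(noor_substrate_params(1e-5, 1e-3),
                        pgi_eq$cSeq, 4.8e-3, pgi_eq), 0)
  expect_identical(
    noor_rate_product(noor_product_params(1e-3, 1e-2),
                      eno_eq$cSeq, 74.8e-3, eno_eq), 0)
  expect_identical(
    noor_rate_double(1e-5, 1e-3, 1e-2, pgi_eq$cSeq, 4.8e-3, pgi_eq), 0)
})

test_that("substrate-saturation curve has no interior local minimum", {
  p <- noor_substrate_params(13.21e-6, 3.26e-3)
  cS <- seq(pgi_eq$cSeq * 1.001, 4.8e-3, length.out = 400)
  r <- noor_rate_substrate(p, cS, 4.8e-3, pgi_eq)
  d <- diff(r)
  # monotone rise: once the derivative turns negative it stays negative
  sign_changes <- sum(diff(sign(d)) != 0)
  expect_lte(sign_changes, 1)
  expect_true(all(r >= 0))
})
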