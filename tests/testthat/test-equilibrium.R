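om3000 <- rpm_to_omega(3000)

test_that("simulated profiles follow the exponential equilibrium law", {
  # massless species: flat profile at baseline + amplitude
  flat <- simulate_se(list(c(M = 0, vbar = 0.73, amplitude = 0.4)),
                      omega = om3000, T = 293.15, rho = 0.998,
                      baseline = 0.1)
  expect_equal(flat$signal, rep(0.5, length(flat$r)), tolerance = 1e-12)
  # single species, noise-free: log signal linear in (r^2 - r_ref^2)/2
  ds <- simulate_se(list(c(M = 1.65e6, vbar = 0.746, amplitude = 0.3)),
                    omega = om3000, T = 277.15, rho = 1.0)
  x <- (ds$r^2 - ds$r_ref^2) / 2
  fit <- stats::lm(log(ds$signal) ~ x)
  expect_gt(suppressWarnings(summary(fit)$r.squared), 1 - 1e-12)
  # slope equals the hand-evaluated reduced buoyant molar mass:
  # 1.65e6 * (1 - 0.746) * (100 pi)^2 / (8.314462618e7 * 277.15)
  expect_equal(unname(stats::coef(fit)[2]), 1.7950163, tolerance = 1e-6)
  expect_error(simulate_se(list(c(M = 1e6, vbar = 1.2, amplitude = 1)),
                           omega = om3000, T = 293, rho = 1), "float")
  expect_error(simulate_se(list(c(M = 1e6, vbar = 0.73, amplitude = 1)),
                           omega = om3000, T = 293, rho = 1,
                           r_grid = seq(4, 5, 0.1)), "window")
})

test_that("sigma scales linearly with M and with omega squared", {
  sig <- function(M, om) pdcore:::se_sigma(M, 0.73, om, 293.15, 0.998)
  expect_equal(sig(2e6, om3000), 2 * sig(1e6, om3000), tolerance = 1e-12)
  expect_equal(sig(1e6, 2 * om3000), 4 * sig(1e6, om3000), tolerance = 1e-12)
})

test_that("simulation is deterministic per seed", {
  mk <- function(seed) simulate_se(list(c(M = 1.65e6, vbar = 0.746,
                                          amplitude = 0.3)),
                                   omega = om3000, T = 277.15, rho = 1.0,
                                   noise_sd = 0.01, seed = seed)
  expect_identical(mk(7), mk(7))
  expect_false(identical(mk(7), mk(8)))
  expect_error(simulate_se(list(c(M = 1e6, vbar = 0.73, amplitude = 1)),
                           omega = om3000, T = 293, rho = 1,
                           noise_sd = 0.01), "seed")
})

test_that("noise-free profiles are fitted to numerical precision", {
  ds <- simulate_se(list(c(M = 1.65e6, vbar = 0.746, amplitude = 0.3)),
                    omega = om3000, T = 277.15, rho = 1.0, baseline = 0.1)
  ft <- suppressWarnings(fit_se(ds, vbar = 0.746))
  expect_rel(ft$Mapp, 1.65e6, 1e-3)
  expect_equal(ft$baseline, 0.1, tolerance = 1e-4)
})

test_that("a two-species fit beats one species on a strong mixture", {
  ds <- simulate_se(list(c(M = 1.65e6, vbar = 0.746, amplitude = 0.27),
                         c(M = 3.3e6, vbar = 0.746, amplitude = 0.03)),
                    omega = om3000, T = 277.15, rho = 1.0,
                    noise_sd = 0.002, seed = 4)
  f1 <- fit_se(ds, vbar = 0.746, n_species = 1)
  f2 <- fit_se(ds, vbar = 0.746, n_species = 2)
  expect_gt(f1$rms, 2 * f2$rms)
  expect_rel(f2$species$M[1], 1.65e6, 0.03)
  expect_lt(abs(f2$species$fraction[1] - 0.9), 0.01)
  expect_equal(sum(f2$species$fraction), 1, tolerance = 1e-12)
})

test_that("mass extrapolation to infinite dilution inverts 1/Mapp", {
  expect_equal(extrapolate_Mw0(c(0.2, 0.5, 0.9), rep(1.65e6, 3))$Mw0,
               1.65e6, tolerance = 1e-6)
  conc <- c(0.2, 0.4, 0.8, 1.2)
  Mapp <- 1 / ((1 / 1.65e6) * (1 + 0.15 * conc))   # linear in 1/M
  expect_equal(extrapolate_Mw0(conc, Mapp)$Mw0, 1.65e6, tolerance = 1e-6)
  expect_error(extrapolate_Mw0(c(0.1, 0.9), c(-2e6, 2.2e6)), "unphysical")
})

test_that("the stderr of Mw0 has near-nominal coverage", {
  conc <- c(0.2, 0.4, 0.8, 1.2)
  inv_true <- (1 / 1.65e6) * (1 + 0.15 * conc)
  set.seed(99)
  covered <- replicate(500, {
    Mapp <- 1 / (inv_true * (1 + stats::rnorm(4, 0, 0.01)))
    ex <- extrapolate_Mw0(conc, Mapp)
    abs(ex$Mw0 - 1.65e6) < ex$stderr
  })
  expect_gt(mean(covered), 0.55)   # ~68% nominal, 4 points only
  expect_lt(mean(covered), 0.85)
})
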