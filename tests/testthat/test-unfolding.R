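test_that("the two-state signal has its midpoint at Cm = dG0/m", {
  # the three construct fixtures: (dG0 kJ/mol, Cm M) pairs imply m = dG0/Cm
  fixtures <- list(c(dG0 = 17.0, Cm = 2.70), c(dG0 = 23.6, Cm = 3.19),
                   c(dG0 = 11.0, Cm = 2.88))
  for (fx in fixtures) {
    m <- fx["dG0"] / fx["Cm"]
    fU <- pdcore:::unfolded_fraction(fx["Cm"], fx["dG0"], m, 298.15)
    expect_equal(unname(fU), 0.5, tolerance = 1e-12)
  }
  # a very stable protein shows only its native baseline in the window
  c <- seq(0, 6, by = 0.5)
  y <- two_state_signal(c, dG0 = 500, m_value = 10,
                        baselines = c(2, -0.05, 0.1, 0))
  expect_equal(y, 2 - 0.05 * c, tolerance = 1e-9)
})

test_that("noise-free curves are fitted to better than 0.1%", {
  c <- seq(0, 6, by = 0.25)
  truth <- list(dG0 = 17, m = 17 / 2.7, bl = c(1, -0.01, 0.05, 0.005))
  crv <- simulate_unfolding(c, truth$dG0, truth$m, truth$bl)
  ft <- fit_two_state(crv)
  expect_rel(ft$dG0, truth$dG0, 1e-3)
  expect_rel(ft$m_value, truth$m, 1e-3)
  expect_equal(ft$Cm, ft$dG0 / ft$m_value, tolerance = 1e-15)
})

test_that("fits are equivariant under affine transforms of the signal", {
  c <- seq(0, 6, by = 0.25)
  crv <- simulate_unfolding(c, 11, 11 / 2.88, c(1, -0.01, 0.05, 0.005),
                            noise_sd = 0.01, seed = 21)
  ft <- fit_two_state(crv)
  crv2 <- unfolding_curve(c, 3.5 * crv$y - 2)
  ft2 <- fit_two_state(crv2)
  expect_equal(ft2$dG0, ft$dG0, tolerance = 1e-6)
  expect_equal(ft2$m_value, ft$m_value, tolerance = 1e-6)
  expect_equal(ft2$baselines[1], 3.5 * ft$baselines[1] - 2, tolerance = 1e-5)
})

test_that("flat and transition-free curves are rejected", {
  c <- seq(0, 6, by = 0.5)
  expect_error(fit_two_state(unfolding_curve(c, rep(1, length(c)))),
               "no transition")
  set.seed(5)
  noisy_flat <- unfolding_curve(c, 1 + stats::rnorm(length(c), 0, 0.05))
  expect_error(fit_two_state(noisy_flat), "no transition")
  expect_error(fit_two_state(unfolding_curve(c(0, 3, 6), c(1, 0.5, 0))),
               "at least 6")
})

test_that("percent change maps baselines to 0/100 and fU to percent", {
  c <- seq(0, 6, by = 0.25)
  crv <- simulate_unfolding(c, 17, 17 / 2.6, c(1, 0, 0, 0))
  pc <- percent_change(crv)
  fU <- pdcore:::unfolded_fraction(c, 17, 17 / 2.6, 298.15)
  expect_equal(pc$y, 100 * fU, tolerance = 1e-6)
  # 50% crossing sits at the generator midpoint (2.6 M fixture)
  cross <- stats::approx(pc$y, c, xout = 50)$y
  expect_equal(cross, 2.6, tolerance = 0.01)
  # halfway signal between sloped baselines maps to 50%
  bl <- c(1, -0.02, 0.2, 0.01)
  crv2 <- simulate_unfolding(c, 11, 11 / 2.88, bl)
  pc2 <- percent_change(crv2)
  mid <- (bl[1] + bl[2] * 2.88 + bl[3] + bl[4] * 2.88) / 2
  y_at_Cm <- stats::approx(c, crv2$y, xout = 2.88)$y
  expect_equal(y_at_Cm, mid, tolerance = 1e-3)
  expect_equal(stats::approx(c, pc2$y, xout = 2.88)$y, 50, tolerance = 0.5)
  expect_error(percent_change(unfolding_curve(c, rep(1, length(c))),
                              method = "endpoints"), "dynamic range")
})

test_that("emission peak and barycentre track spectral shifts", {
  wl <- seq(310, 450, by = 1)
  gauss <- function(mu) exp(-(wl - mu)^2 / (2 * 10^2))
  es <- emission_shift(wl, cbind(gauss(330), gauss(345), gauss(360)),
                       c(0, 3, 6))
  expect_equal(es$peak, c(330, 345, 360), tolerance = 0.01)
  # fixture endpoints: folded 330 nm, fully unfolded 360 nm
  expect_equal(es$peak[c(1, 3)], c(330, 360), tolerance = 0.01)
  expect_false(any(es$peak_flag))
  # translation equivariance of both metrics
  es5 <- emission_shift(wl, cbind(gauss(335), gauss(350)), c(0, 6))
  expect_equal(es5$peak[1] - es$peak[1], 5, tolerance = 0.01)
  expect_equal(es5$barycentre[1] - es$barycentre[1], 5, tolerance = 0.1)
  # bimodal spectrum flags the peak but still reports a barycentre
  bim <- emission_shift(wl, cbind(gauss(330) + 0.95 * gauss(400)), 0)
  expect_true(bim$peak_flag[1])
  expect_true(is.finite(bim$barycentre[1]))
})
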