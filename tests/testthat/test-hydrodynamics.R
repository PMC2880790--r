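test_that("anhydrous radii reproduce the published parameter table", {
  expect_lt(abs(anhydrous_radius(molecular_params(3551100, 0.744)) - 102), 1)
  expect_lt(abs(anhydrous_radius(molecular_params(3741780, 0.744)) - 103), 1)
  # the truncated-core row prints 791 where its own f/f0 and Rs imply
  # 79.1 A (a dropped decimal point); the computed value is asserted
  expect_lt(abs(anhydrous_radius(molecular_params(1671348, 0.746)) - 79.1),
            0.1)
  # cube-root scaling: 8x mass doubles the radius
  p <- molecular_params(1e6, 0.73)
  expect_equal(anhydrous_radius(molecular_params(8e6, 0.73)),
               2 * anhydrous_radius(p), tolerance = 1e-12)
})

test_that("Svedberg-derived parameters are internally consistent", {
  h <- svedberg_params(molecular_params(tbl_tE2_E3BP["M"],
                                        tbl_tE2_E3BP["vbar"]),
                       tbl_tE2_E3BP["s"])
  expect_equal(h$Ds, 2 * h$Rs)
  expect_gte(h$f_over_f0, 1)
  # round trip: s recomputed from the reported friction
  s_back <- h$M * (1 - h$vbar * 0.99823) / (6.02214076e23 * h$f) / 1e-13
  expect_equal(s_back, h$s20w0, tolerance = 1e-12)
  # a particle sedimenting exactly like its anhydrous sphere has f/f0 = 1
  p <- molecular_params(2e6, 0.74)
  s_sphere <- p$M * (1 - p$vbar * 0.99823) /
    (6.02214076e23 * svedberg_params(p, 10)$f0) / 1e-13
  expect_equal(svedberg_params(p, s_sphere)$f_over_f0, 1, tolerance = 1e-12)
  expect_error(suppressWarnings(svedberg_params(molecular_params(1e6, 1.2),
                                                10)), "float")
})

test_that("s standardization applies the viscosity-buoyancy product", {
  w20 <- water20()
  expect_equal(standardize_s(29.3, w20, 0.744), 29.3)
  thick <- solvent_conditions(T = w20$T, rho = w20$rho, eta = 2 * w20$eta)
  expect_equal(standardize_s(10, thick, 0.744), 20)
  # 4 C water, checked against a direct evaluation of the product formula
  cold <- solvent_conditions(T = 277.15, rho = 0.99997, eta = 0.01567)
  expected <- 10 * (0.01567 / 0.01002) *
    ((1 - 0.744 * 0.99823) / (1 - 0.744 * 0.99997))
  expect_equal(standardize_s(10, cold, 0.744), expected, tolerance = 1e-12)
})

test_that("infinite-dilution extrapolation of s is exact and unbiased", {
  expect_equal(extrapolate_s0(c(0.1, 0.4, 0.9), rep(27.5, 3))$s0, 27.5,
               tolerance = 1e-9)
  conc <- c(0.2, 0.5, 1.0, 2.0)
  s <- 29.3 * (1 - 0.008 * conc)
  ex <- extrapolate_s0(conc, s)
  expect_equal(ex$s0, 29.3, tolerance = 1e-9)
  expect_warning(out <- extrapolate_s0(1, 27), "single")
  expect_identical(out$stderr, Inf)
  # Monte-Carlo: intercept bias far below its standard error
  set.seed(42)
  s0_hat <- replicate(500, {
    ex <- extrapolate_s0(conc, s + stats::rnorm(4, 0, 0.1))
    ex$s0
  })
  expect_lt(abs(mean(s0_hat) - 29.3), 3 * stats::sd(s0_hat) / sqrt(500))
  # reciprocal variant agrees on noise-free linear data
  expect_equal(extrapolate_s0(conc, s, reciprocal = TRUE)$s0, 29.3,
               tolerance = 1e-3)
})

test_that("hydration conversion factor matches the published value", {
  expect_lt(abs(hydration_factor(0.744, 0.4, 1.002) - 0.87), 0.005)
  expect_lt(abs(hydration_factor(0.746, 0.4, 1.002) - 0.87), 0.005)
  expect_identical(hydration_factor(0.744, 0), 1)
  d <- seq(0, 1, by = 0.1)
  expect_true(all(diff(hydration_factor(0.744, d)) < 0))
})

test_that("cubic-grid coarse-graining conserves volume and collapses cells", {
  pts <- fixture_ball_points()
  V <- 2e6
  cg <- coarse_grain(pts, grid_spacing = 15, target_volume = V)
  expect_rel(model_volume(cg), V, 1e-9)
  expect_lte(nrow(cg$beads), nrow(pts))
  # degenerate grid: one cell -> one bead of radius (3V/4pi)^(1/3)
  cg1 <- coarse_grain(pts, grid_spacing = 1e4, target_volume = V)
  expect_identical(nrow(cg1$beads), 1L)
  expect_equal(cg1$beads$radius, (3 * V / (4 * pi))^(1 / 3),
               tolerance = 1e-9)
  expect_equal(unlist(cg1$beads[1, c("x", "y", "z")], use.names = FALSE),
               colMeans(pts), tolerance = 1e-9)
  expect_error(coarse_grain(matrix(numeric(0), ncol = 3), 10, 1), "empty")
})

test_that("single-bead friction is Stokes law for both methods", {
  a <- 20
  f_stokes <- 6 * pi * 0.01002 * a * 1e-8
  m <- bead_model(3, -8, 12, radius = a)
  expect_equal(bead_friction(m, method = "supermatrix"), f_stokes,
               tolerance = 1e-12)
  expect_equal(bead_friction(m, method = "kirkwood"), f_stokes,
               tolerance = 1e-12)
})

test_that("two touching spheres match the independent two-body solution", {
  a <- 20
  m <- bead_model(c(0, 0), c(0, 0), c(0, 2 * a), radius = a)
  # by symmetry both beads carry the same force, so the 6x6 system reduces
  # to a 3x3 one per axis with RPY eigen-mobilities along/normal to the axis
  eta <- 0.01002
  acm <- a * 1e-8
  r <- 2 * acm
  xi <- 6 * pi * eta * acm
  C1 <- 1 / (8 * pi * eta * r)
  t_par <- C1 * (2 - 4 * acm^2 / (3 * r^2))
  t_perp <- C1 * (1 + 2 * acm^2 / (3 * r^2))
  f_closed <- (2 / (1 / xi + t_par) + 4 / (1 / xi + t_perp)) / 3
  expect_equal(bead_friction(m), f_closed, tolerance = 1e-12)
})

test_that("Kirkwood approximation tracks the supermatrix within 10%", {
  for (m in list(fixture_shell(), fixture_core(seed = 1),
                 coarse_grain(fixture_ball_points(), 20, 1e6))) {
    fs <- suppressMessages(bead_friction(m, method = "supermatrix"))
    fk <- bead_friction(m, method = "kirkwood")
    expect_lt(abs(fk / fs - 1), 0.10)
  }
})

test_that("friction is invariant under rigid motion and flags overlap", {
  m <- fixture_core(seed = 2)
  th <- 1.1
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)), 3, 3)
  expect_equal(bead_friction(transform_model(m, R, c(11, -7, 3))),
               bead_friction(m), tolerance = 1e-12)
  overlapping <- bead_model(c(0, 0), c(0, 0), c(0, 25), radius = 20)
  expect_message(bead_friction(overlapping), "shrunk")
})

test_that("bead-model sedimentation obeys its sphere limit and F scaling", {
  p <- molecular_params(1671348, 0.746, delta1 = 0.4)
  R0 <- anhydrous_radius(p)
  one <- bead_model(0, 0, 0, radius = R0)
  sed <- model_sedimentation(one, p)
  # single anhydrous sphere: s_anh equals the closed-form f/f0 = 1 value
  s_closed <- p$M * (1 - p$vbar * 0.99823) /
    (6.02214076e23 * 6 * pi * 0.01002 * R0 * 1e-8) / 1e-13
  expect_equal(sed$s_anh, s_closed, tolerance = 1e-9)
  expect_equal(sed$s_hyd / sed$s_anh, sed$F, tolerance = 1e-12)
  expect_equal(sed$F, hydration_factor(0.746, 0.4, 1 / 0.99823),
               tolerance = 1e-12)
})

test_that("friction is stable between 7 and 5.7 Angstrom grids", {
  armed <- fixture_armed(1)
  V <- particle_volume(1671348, 0.746)
  f7 <- suppressMessages(bead_friction(coarse_grain(armed, 7, V),
                                       method = "kirkwood"))
  f57 <- suppressMessages(bead_friction(coarse_grain(armed, 5.7, V),
                                        method = "kirkwood"))
  expect_lt(abs(f7 / f57 - 1), 0.05)
})
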