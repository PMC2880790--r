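# shared fixture builders; everything is generated in code, nothing stored

fixture_sphere <- function(R = 50) {
  bead_model(0, 0, 0, radius = R, label = "sphere")
}

# golden-spiral shell of point-like beads on a sphere of radius R
fixture_shell <- function(R = 100, n = 42, bead_radius = 10) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  r <- sqrt(1 - z^2)
  ga <- pi * (3 - sqrt(5))
  bead_model(R * r * cos(ga * i), R * r * sin(ga * i), R * z,
             radius = bead_radius, label = "shell")
}

fixture_core <- function(seed = 1, model = "substitution_48_12") {
  build_core_model(assembly_spec(model, seed = seed))
}

fixture_armed <- function(seed = 1) {
  add_flexible_arms(fixture_core(seed), arm_spec(), seed = seed)
}

# dense uniform-ball point cloud for coarse-graining tests
fixture_ball_points <- function(R = 60, n = 4000, seed = 7) {
  set.seed(seed)
  pts <- matrix(stats::rnorm(3 * n * 2), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * R * stats::runif(2 * n)^(1 / 3)
  pts[seq_len(n), ]
}

# Table rows used throughout: M (Da), vbar (mL/g), s20w0 (S)
tbl_rE2_E3BP <- c(M = 3551100, vbar = 0.744, s = 29.3)
tbl_rE2      <- c(M = 3741780, vbar = 0.744, s = 29.3)
tbl_tE2_E3BP <- c(M = 1671348, vbar = 0.746, s = 27.5)

expect_rel <- function(object, expected, tol, ...) {
  expect_lt(abs(object / expected - 1), tol, ...)
}
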