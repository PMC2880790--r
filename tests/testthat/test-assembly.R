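test_that("chain census matches each stoichiometry model", {
  census <- function(model) {
    b <- model$beads
    table(b$subunit[!duplicated(b$chain)])
  }
  sub <- fixture_core(seed = 3)
  cs <- census(sub)
  expect_identical(as.integer(cs[["E2"]]), 48L)
  expect_identical(as.integer(cs[["E3BP"]]), 12L)
  expect_identical(length(unique(sub$beads$chain)), 60L)

  e2 <- build_core_model(assembly_spec("E2_only_60", seed = 3))
  expect_identical(as.integer(census(e2)[["E2"]]), 60L)
  expect_false("E3BP" %in% names(census(e2)))
  expect_identical(nrow(e2$beads), 60L)  # 20 trimers x 3 monomers x 1 bead

  add <- build_core_model(assembly_spec("addition_60_12", seed = 3))
  ca <- census(add)
  expect_identical(as.integer(ca[["E2"]]), 60L)
  expect_identical(as.integer(ca[["E3BP"]]), 12L)  # face clusters
  expect_identical(length(unique(add$beads$chain)), 72L)
})

test_that("trimers sit on 20 distinct dodecahedron vertices", {
  m <- build_core_model(assembly_spec("E2_only_60", seed = 1))
  b <- m$beads
  centroids <- t(vapply(split(seq_len(nrow(b)), (b$chain - 1L) %/% 3L),
                        function(i) colMeans(cbind(b$x, b$y, b$z)[i, ]),
                        numeric(3)))
  expect_identical(nrow(unique(round(centroids, 6))), 20L)
  # every trimer centroid lies at inner_radius from the origin
  expect_equal(unname(sqrt(rowSums(centroids^2))), rep(125, 20),
               tolerance = 1e-9)
})

test_that("core is hollow and pentagonal faces are open (or occupied)", {
  for (sm in c("E2_only_60", "substitution_48_12")) {
    m <- build_core_model(assembly_spec(sm, seed = 2))
    radial <- sqrt(rowSums(bead_coords(m)^2))
    expect_gt(min(radial), 0.5 * 125)
    axes <- pdcore:::pentagonal_face_axes()
    unit <- bead_coords(m) / radial
    ang <- acos(pmin(1, abs(unit %*% t(axes))))   # bead-to-axis angles
    expect_gt(min(ang) * 180 / pi, 20)            # open cap of 20 degrees
  }
  add <- build_core_model(assembly_spec("addition_60_12", seed = 2))
  radial <- sqrt(rowSums(bead_coords(add)^2))
  unit <- bead_coords(add) / radial
  ang <- acos(pmin(unit %*% t(pdcore:::pentagonal_face_axes()), 1))
  expect_true(all(apply(ang * 180 / pi, 2, min) < 1))  # every face occupied
  expect_gt(min(radial), 0.5 * 125)                    # still hollow
})

test_that("construction is deterministic for a fixed spec and seed", {
  s <- assembly_spec("substitution_48_12", seed = 11)
  expect_identical(build_core_model(s), build_core_model(s))
  core <- build_core_model(s)
  expect_identical(add_flexible_arms(core, arm_spec(), seed = 5),
                   add_flexible_arms(core, arm_spec(), seed = 5))
  a5 <- add_flexible_arms(core, arm_spec(), seed = 5)
  a6 <- add_flexible_arms(core, arm_spec(), seed = 6)
  expect_false(identical(a5, a6))
})

test_that("arms extend the particle and obey the counting identities", {
  core <- fixture_core(seed = 1)
  expect_identical(add_flexible_arms(core, arm_spec(beads_per_arm = 0), 1),
                   core)
  expect_identical(add_flexible_arms(core, arm_spec(n_arms = 0), 1), core)
  a <- add_flexible_arms(core, arm_spec(n_arms = 12, beads_per_arm = 10),
                         seed = 4)
  expect_identical(nrow(a$beads) - nrow(core$beads), 120L)
  expect_gt(model_dmax(a), model_dmax(core))
})

test_that("composition mass is an exact, linear, symmetric bookkeeping", {
  ms <- subunit_masses(m_E2 = 61000, m_E3BP = 50000)
  expect_identical(composition_mass(c(E2 = 3), ms), 183000)
  expect_identical(composition_mass(numeric(0), ms), 0)
  expect_error(composition_mass(c(E9 = 1), ms), "unknown subunit")
  expect_error(composition_mass(c(E2 = -1), ms), ">= 0")
  expect_error(composition_mass(c(tE2 = 1), ms), "mass not set")
  # linearity and permutation symmetry
  set.seed(1)
  for (i in 1:10) {
    n1 <- sample(0:60, 2)
    st <- c(E2 = n1[1], E3BP = n1[2])
    expect_equal(composition_mass(2 * st, ms), 2 * composition_mass(st, ms))
    expect_equal(composition_mass(rev(st), ms), composition_mass(st, ms))
  }
  # dimer of the truncated 48+12 core
  expect_identical(oligomer_mass(1671348, 2), 3342696)
})

test_that("particle volume follows M vbar / N_A with unit conversion", {
  expect_rel(particle_volume(3551100, 0.744), 4.38e6, 0.005)
  expect_rel(particle_volume(1671348, 0.746), 2.0704e6, 1e-3)
  expect_equal(particle_volume(2e6, 0.73), 2 * particle_volume(1e6, 0.73))
})

test_that("invalid assembly specifications are rejected with clear errors", {
  expect_error(assembly_spec("tetramer_model"), "arg")
  expect_error(build_core_model(list()), "assembly_spec")
  expect_error(bead_model(numeric(0), numeric(0), numeric(0), 1),
               "at least one bead")
  expect_error(bead_model(0, 0, 0, radius = -1), "positive")
  expect_error(subunit_masses(m_E2 = 61000, m_tE2 = 70000), "smaller")
})
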