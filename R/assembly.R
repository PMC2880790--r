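#' Subunit masses
#'
#' Monomer masses of the core subunits (Da). Full-length and truncated chains
#' are held separately; truncated masses, when supplied, must be smaller than
#' their full-length counterparts. Defaults are the gel-estimated monomer
#' masses of recombinant E2 (61 kDa) and E3BP (50 kDa); truncated masses have
#' no default and must be given explicitly where needed, because published
#' per-chain and per-core totals cannot be reconciled into a single set.
#'
#' @param m_E2,m_E3BP full-length chain masses (Da).
#' @param m_tE2,m_tE3BP truncated chain masses (Da), optional.
#' @return An object of class `subunit_masses`.
#' @examples
#' subunit_masses()
#' @export
subunit_masses <- function(m_E2 = 61000, m_E3BP = 50000,
                           m_tE2 = NA_real_, m_tE3BP = NA_real_) {
  stopifnot(m_E2 > 0, m_E3BP > 0)
  if (!is.na(m_tE2) && (m_tE2 <= 0 || m_tE2 >= m_E2))
    stop("m_tE2 must be positive and smaller than m_E2")
  if (!is.na(m_tE3BP) && (m_tE3BP <= 0 || m_tE3BP >= m_E3BP))
    stop("m_tE3BP must be positive and smaller than m_E3BP")
  structure(list(m_E2 = m_E2, m_E3BP = m_E3BP,
                 m_tE2 = m_tE2, m_tE3BP = m_tE3BP),
            class = "subunit_masses")
}

#' Arm specification
#'
#' Describes the flexible N-terminal arms appended to a core model: how many
#' arms, how many beads each, the bead spacing along the arm and the arm bead
#' radius. The defaults are calibrated so that arms raise the maximum
#' dimension of the default core (about 300 A) to about 480 A, i.e. the arms
#' account for roughly 40 percent of the overall Dmax.
#'
#' @param n_arms arms per assembly (default 60, one per chain).
#' @param beads_per_arm beads in each arm.
#' @param spacing centre-centre bead spacing along an arm (Angstrom).
#' @param bead_radius arm bead radius (Angstrom).
#' @param jitter_sd angular diffusion per step (radians) of the outward
#'   persistent walk that traces each arm; 0 gives straight radial arms.
#' @return An object of class `arm_spec`.
#' @export
arm_spec <- function(n_arms = 60, beads_per_arm = 10, spacing = 9.5,
                     bead_radius = 5, jitter_sd = 0.15) {
  stopifnot(n_arms >= 0, beads_per_arm >= 0, spacing > 0, bead_radius > 0,
            jitter_sd >= 0)
  structure(list(n_arms = n_arms, beads_per_arm = beads_per_arm,
                 spacing = spacing, bead_radius = bead_radius,
                 jitter_sd = jitter_sd),
            class = "arm_spec")
}

#' Assembly specification
#'
#' Recipe for a synthetic pentagonal-dodecahedral 60-mer: 20 trimer positions
#' on the vertices of a regular dodecahedron (equivalently, the face centres
#' of its dual icosahedron), each holding three monomer beads, with the
#' stoichiometry controlled by `stoichiometry_model`:
#'
#' * `"E2_only_60"` - 60 E2 chains, nothing on the pentagonal faces;
#' * `"substitution_48_12"` - 12 E3BP chains replace 12 E2 chains (one per
#'   heterotrimer at 12 seeded vertices), faces stay open;
#' * `"addition_60_12"` - 60 E2 chains plus 12 extra E3BP density clusters
#'   centred on the 12 pentagonal face axes.
#'
#' Geometry defaults are calibration constants, not measurements: with
#' `inner_radius = 125`, `trimer_edge = 40` and `bead_radius = 20` the core
#' model has Dmax of about 300 A and a total bead volume of about 2.07e6 A^3,
#' matching the anhydrous volume of the truncated E2/E3BP core.
#'
#' @param stoichiometry_model one of `"E2_only_60"`, `"substitution_48_12"`,
#'   `"addition_60_12"`.
#' @param inner_radius distance from the particle centre to each trimer
#'   centroid (Angstrom).
#' @param trimer_edge edge length of the equilateral monomer triangle at each
#'   vertex (Angstrom).
#' @param bead_radius monomer bead radius (Angstrom).
#' @param beads_per_monomer beads representing one monomer (stacked radially
#'   when larger than 1).
#' @param arm_spec optional [arm_spec()]; arms are appended by
#'   [add_flexible_arms()] when [build_core_model()] is called with
#'   `with_arms = TRUE`.
#' @param seed integer seed controlling the (deterministic) choice of
#'   heterotrimer vertices and arm anchors.
#' @return An object of class `assembly_spec`.
#' @examples
#' assembly_spec("substitution_48_12", seed = 1)
#' @export
assembly_spec <- function(stoichiometry_model = c("substitution_48_12",
                                                  "E2_only_60",
                                                  "addition_60_12"),
                          inner_radius = 125, trimer_edge = 40,
                          bead_radius = 20, beads_per_monomer = 1,
                          arm_spec = NULL, seed = 1) {
  stoichiometry_model <- match.arg(stoichiometry_model)
  stopifnot(inner_radius > 0, trimer_edge > 0, bead_radius > 0,
            beads_per_monomer >= 1)
  if (!is.null(arm_spec) && !inherits(arm_spec, "arm_spec"))
    stop("arm_spec must be built with arm_spec()")
  structure(list(n_vertices = 20L,
                 stoichiometry_model = stoichiometry_model,
                 inner_radius = inner_radius, trimer_edge = trimer_edge,
                 bead_radius = bead_radius,
                 beads_per_monomer = as.integer(beads_per_monomer),
                 arm_spec = arm_spec, seed = seed),
            class = "assembly_spec")
}

# unit vertices of a regular dodecahedron (20, the trimer positions)
dodecahedron_vertices <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    cbind(0, c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi)),
    cbind(c(-1, -1, 1, 1) / phi, c(-phi, phi, -phi, phi), 0),
    cbind(c(-phi, phi, -phi, phi), 0, c(-1, -1, 1, 1) / phi)
  )
  v / sqrt(rowSums(v^2))
}

# unit face axes of the dodecahedron (12 pentagonal faces = vertices of the
# dual icosahedron, in the orientation matching dodecahedron_vertices)
pentagonal_face_axes <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(cbind(0, c(-phi, phi, -phi, phi), c(-1, -1, 1, 1)),
             cbind(c(-phi, phi, -phi, phi), c(-1, -1, 1, 1), 0),
             cbind(c(-1, -1, 1, 1), 0, c(-phi, phi, -phi, phi)))
  v / sqrt(rowSums(v^2))
}

# orthonormal tangent frame at unit vector n; deterministic
tangent_frame <- function(n) {
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- c(ref[2] * n[3] - ref[3] * n[2],
         ref[3] * n[1] - ref[1] * n[3],
         ref[1] * n[2] - ref[2] * n[1])
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' Build a synthetic dodecahedral core bead model
#'
#' Places 20 trimers of monomer beads on the vertices of a regular
#' dodecahedron at `spec$inner_radius`, assigns subunit identities according
#' to the stoichiometry model, and (for the addition model only) adds 12
#' E3BP clusters on the pentagonal face axes. The centre of the particle and
#' the pentagonal faces are left empty for the E2-only and substitution
#' models, reproducing the hollow, open-faced morphology seen for these
#' assemblies. Deterministic for a fixed `spec` (including its seed).
#'
#' @param spec an [assembly_spec()].
#' @param with_arms append flexible arms per `spec$arm_spec` (default FALSE).
#' @return A [bead_model()] with per-bead `subunit` and `chain` annotations.
#' @examples
#' core <- build_core_model(assembly_spec("substitution_48_12", seed = 7))
#' table(core$beads$subunit)
#' @export
build_core_model <- function(spec, with_arms = FALSE) {
  if (!inherits(spec, "assembly_spec"))
    stop("spec must be built with assembly_spec(); got ",
         paste(class(spec), collapse = "/"))
  verts <- dodecahedron_vertices() * spec$inner_radius
  t_circ <- spec$trimer_edge / sqrt(3)  # triangle circumradius

  # substitution model: 12 of the 20 trimers carry one E3BP (2E2 + 1E3BP)
  hetero <- rep(FALSE, 20)
  if (spec$stoichiometry_model == "substitution_48_12")
    hetero[with_seed(spec$seed, sample.int(20, 12))] <- TRUE

  xs <- ys <- zs <- numeric(0)
  sub <- character(0); chn <- integer(0)
  chain_id <- 0L
  for (k in seq_len(20)) {
    n <- verts[k, ] / sqrt(sum(verts[k, ]^2))
    fr <- tangent_frame(n)
    for (m in 0:2) {
      chain_id <- chain_id + 1L
      th <- 2 * pi * m / 3
      centre <- verts[k, ] + t_circ * (cos(th) * fr$u + sin(th) * fr$v)
      # monomers with >1 bead are stacked outward along the radial axis
      for (b in seq_len(spec$beads_per_monomer)) {
        pos <- centre + (b - 1L) * 2 * spec$bead_radius * n
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2]); zs <- c(zs, pos[3])
        sub <- c(sub, if (hetero[k] && m == 0L) "E3BP" else "E2")
        chn <- c(chn, chain_id)
      }
    }
  }

  if (spec$stoichiometry_model == "addition_60_12") {
    axes <- pentagonal_face_axes() * spec$inner_radius
    for (k in seq_len(12)) {
      chain_id <- chain_id + 1L
      n <- axes[k, ] / sqrt(sum(axes[k, ]^2))
      for (b in seq_len(spec$beads_per_monomer)) {
        pos <- axes[k, ] + (b - 1L) * 2 * spec$bead_radius * n
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2]); zs <- c(zs, pos[3])
        sub <- c(sub, "E3BP"); chn <- c(chn, chain_id)
      }
    }
  }

  model <- bead_model(xs, ys, zs, radius = spec$bead_radius, weight = 1,
                      subunit = sub, chain = chn,
                      label = spec$stoichiometry_model)
  if (isTRUE(with_arms) && !is.null(spec$arm_spec))
    model <- add_flexible_arms(model, spec$arm_spec, seed = spec$seed)
  model
}

#' Append flexible arms to a core model
#'
#' Emulates the disordered N-terminal linker/lipoyl-domain arms that emanate
#' outward from the icosahedral inner core: each arm is a persistent outward
#' random walk of beads anchored at a randomly chosen surface bead. Arms are
#' only self-avoiding with respect to their previous bead (they are meant to
#' be flexible and disordered); full excluded volume is not enforced.
#' Deterministic for a fixed seed. With zero arms or zero beads per arm the
#' input model is returned unchanged.
#'
#' @param core a [bead_model()].
#' @param arms an [arm_spec()].
#' @param seed integer seed.
#' @return A `bead_model` with `arms$n_arms * arms$beads_per_arm` extra beads
#'   (subunit label `"arm"`).
#' @examples
#' core <- build_core_model(assembly_spec(seed = 1))
#' armed <- add_flexible_arms(core, arm_spec(), seed = 1)
#' model_dmax(armed) > model_dmax(core)
#' @export
add_flexible_arms <- function(core, arms, seed) {
  stopifnot(inherits(core, "bead_model"), inherits(arms, "arm_spec"))
  if (arms$n_arms == 0L || arms$beads_per_arm == 0L) return(core)

  b <- core$beads
  radial <- sqrt(b$x^2 + b$y^2 + b$z^2)
  # outer-shell anchors (tolerance so a shell of equal radii is all eligible)
  surface <- which(radial >= stats::median(radial) * (1 - 1e-9))
  new <- with_seed(seed, {
    anchors <- sample(surface, arms$n_arms, replace = arms$n_arms > length(surface))
    out <- vector("list", arms$n_arms)
    for (a in seq_len(arms$n_arms)) {
      i <- anchors[a]
      pos <- c(b$x[i], b$y[i], b$z[i])
      dir <- pos / sqrt(sum(pos^2))
      dir <- dir + arms$jitter_sd * stats::rnorm(3)  # arms start splayed
      dir <- dir / sqrt(sum(dir^2))
      # first bead sits on the anchor bead surface, then fixed spacing
      pts <- matrix(NA_real_, arms$beads_per_arm, 3)
      step <- b$radius[i] + arms$bead_radius
      for (k in seq_len(arms$beads_per_arm)) {
        pos <- pos + step * dir
        pts[k, ] <- pos
        dir <- dir + arms$jitter_sd * stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        step <- arms$spacing
      }
      out[[a]] <- pts
    }
    do.call(rbind, out)
  })

  n_new <- nrow(new)
  max_chain <- max(b$chain, 0L, na.rm = TRUE)
  add <- data.frame(x = new[, 1], y = new[, 2], z = new[, 3],
                    radius = arms$bead_radius, weight = 1,
                    subunit = "arm",
                    chain = max_chain + rep(seq_len(arms$n_arms),
                                            each = arms$beads_per_arm))
  core$beads <- rbind(b, add)
  core$label <- paste0(core$label, "+arms")
  core
}

#' Composition mass bookkeeping
#'
#' `composition_mass` computes the exact weighted sum of chain counts times
#' chain masses for a stoichiometry given as a named count vector with names
#' among `E2`, `E3BP`, `tE2`, `tE3BP`. `oligomer_mass` is the thin multiple
#' used for dimers-of-cores and trimers.
#'
#' @param stoichiometry named numeric vector of non-negative chain counts.
#' @param masses a [subunit_masses()].
#' @return Total mass in Da.
#' @examples
#' composition_mass(c(E2 = 3), subunit_masses(m_E2 = 61000))   # 183 kDa trimer
#' oligomer_mass(1671348, 2)                                   # core dimer
#' @export
composition_mass <- function(stoichiometry, masses = subunit_masses()) {
  if (length(stoichiometry) == 0L) return(0)
  stopifnot(inherits(masses, "subunit_masses"))
  keys <- names(stoichiometry)
  known <- c(E2 = masses$m_E2, E3BP = masses$m_E3BP,
             tE2 = masses$m_tE2, tE3BP = masses$m_tE3BP)
  if (is.null(keys) || any(!keys %in% names(known)))
    stop("unknown subunit key(s): ",
         paste(setdiff(keys, names(known)), collapse = ", "))
  if (any(stoichiometry < 0)) stop("chain counts must be >= 0")
  m <- known[keys]
  if (any(is.na(m) & stoichiometry > 0))
    stop("mass not set for subunit(s): ",
         paste(keys[is.na(m) & stoichiometry > 0], collapse = ", "))
  sum(stoichiometry * m, na.rm = TRUE)
}

#' @rdname composition_mass
#' @param core_mass mass of one core (Da).
#' @param n_copies number of cores in the oligomer.
#' @export
oligomer_mass <- function(core_mass, n_copies) {
  stopifnot(core_mass > 0, n_copies >= 0)
  n_copies * core_mass
}

#' Anhydrous particle volume
#'
#' Converts a molar mass and partial specific volume into the particle
#' volume `V = M * vbar / N_A`, expressed in Angstrom^3.
#'
#' @param M molar mass (Da).
#' @param vbar partial specific volume (mL/g).
#' @return Volume in Angstrom^3.
#' @examples
#' particle_volume(3551100, 0.744)  # ~4.38e6 A^3
#' @export
particle_volume <- function(M, vbar) {
  stopifnot(M > 0, vbar > 0)
  M * vbar / .N_A * 1e24
}
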