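#' Cubic-grid coarse-graining of coordinates into a bead model
#'
#' Lays a cubic grid of spacing `grid_spacing` over the bounding box of the
#' input points; all points falling in one cell collapse to a single bead at
#' their weighted centroid, with bead volume proportional to the cell's
#' point mass. All bead radii are then rescaled by a common factor so the
#' total bead volume equals `target_volume` exactly.
#'
#' @param points a [bead_model()] or an n x 3 coordinate matrix (Angstrom).
#' @param grid_spacing cubic cell edge (Angstrom).
#' @param target_volume total anhydrous volume to enforce (Angstrom^3).
#' @param weights optional per-point masses (default: bead scattering masses
#'   for a bead model, 1 otherwise).
#' @return A [bead_model()] with one bead per occupied cell.
#' @export
coarse_grain <- function(points, grid_spacing, target_volume, weights = NULL) {
  stopifnot(grid_spacing > 0, target_volume > 0)
  if (inherits(points, "bead_model")) {
    if (is.null(weights)) weights <- bead_masses(points)
    points <- bead_coords(points)
  }
  points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty input: nothing to coarse-grain")
  if (is.null(weights)) weights <- rep(1, nrow(points))

  lo <- apply(points, 2, min)
  cell <- floor(sweep(points, 2, lo) / grid_spacing)
  key <- paste(cell[, 1], cell[, 2], cell[, 3])
  groups <- split(seq_len(nrow(points)), key)

  n <- length(groups)
  xyz <- matrix(NA_real_, n, 3)
  mass <- numeric(n)
  for (k in seq_along(groups)) {
    i <- groups[[k]]
    w <- weights[i]
    xyz[k, ] <- colSums(points[i, , drop = FALSE] * w) / sum(w)
    mass[k] <- sum(w)
  }
  vol <- target_volume * mass / sum(mass)
  radius <- (3 * vol / (4 * pi))^(1 / 3)
  # enforced by construction, but guard against numerical drift
  radius <- radius * (target_volume / sum((4 / 3) * pi * radius^3))^(1 / 3)
  bead_model(xyz[, 1], xyz[, 2], xyz[, 3], radius = radius, weight = 1,
             label = sprintf("coarse-grained (%g A grid)", grid_spacing))
}

#' Translational friction coefficient of a bead model
#'
#' Computes the translational friction coefficient `f_t` (g/s) of a rigid
#' bead model in a solvent, by either:
#'
#' * `"supermatrix"` (default): builds the 3N x 3N pair mobility matrix from
#'   Rotne-Prager-Yamakawa tensors (with single-bead Stokes blocks on the
#'   diagonal), solves for the bead forces under unit uniform velocity, and
#'   averages the total force over the three axes. Beads must not overlap;
#'   overlapping models have all radii uniformly shrunk to the largest
#'   non-overlapping scale (with a message) because the plain RPY tensor
#'   assumes non-overlapping spheres.
#' * `"kirkwood"`: the orientationally preaveraged double-sum approximation
#'   `f_t = N^2 / (sum_i 1/xi_i + sum_(i != j) 1/(6 pi eta r_ij))`, with
#'   `xi_i = 6 pi eta a_i`.
#'
#' Both are invariant under rigid motion of the model. Rotation-translation
#' coupling is neglected (the force is averaged at fixed orientation), a
#' known small bias for near-spherical assemblies.
#'
#' @param model a [bead_model()].
#' @param solvent a [solvent_conditions()].
#' @param method `"supermatrix"` or `"kirkwood"`.
#' @return f_t in g/s.
#' @examples
#' bead_friction(bead_model(0, 0, 0, radius = 20), water20())
#' @export
bead_friction <- function(model, solvent = water20(),
                          method = c("supermatrix", "kirkwood")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "bead_model"),
            inherits(solvent, "solvent_conditions"))
  xyz <- bead_coords(model) * .CM_PER_ANGSTROM
  a <- model$beads$radius * .CM_PER_ANGSTROM
  n <- length(a)
  eta <- solvent$eta
  xi <- 6 * pi * eta * a

  if (n == 1L) return(xi)

  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- sequence((n - 1):1) + ii
  dx <- xyz[jj, , drop = FALSE] - xyz[ii, , drop = FALSE]
  r <- sqrt(rowSums(dx^2))
  if (any(r == 0)) stop("coincident bead centres: singular configuration")

  if (method == "kirkwood") {
    return(n^2 / (sum(1 / xi) + 2 * sum(1 / (6 * pi * eta * r))))
  }

  # supermatrix: shrink radii if any pair overlaps (plain RPY assumes none)
  ratio <- r / (a[ii] + a[jj])
  if (min(ratio) < 1 - 1e-9) {
    scale <- min(ratio)
    message(sprintf("overlapping beads: radii uniformly shrunk by factor %.4f", scale))
    a <- a * scale
    xi <- xi * scale
  }

  B <- matrix(0, 3 * n, 3 * n)
  a2s <- a[ii]^2 + a[jj]^2
  C1 <- 1 / (8 * pi * eta * r)
  Ac <- C1 * (1 + a2s / (3 * r^2))
  Bc <- C1 * (1 - a2s / r^2)
  rh <- dx / r
  for (p in 1:3) {
    for (qq in 1:3) {
      val <- Bc * rh[, p] * rh[, qq] + if (p == qq) Ac else 0
      rows <- 3 * (ii - 1) + p
      cols <- 3 * (jj - 1) + qq
      B[cbind(rows, cols)] <- val
      B[cbind(3 * (jj - 1) + p, 3 * (ii - 1) + qq)] <- val
    }
  }
  diag(B) <- rep(1 / xi, each = 3)

  U <- matrix(0, 3 * n, 3)
  for (ax in 1:3) U[seq(ax, 3 * n, by = 3), ax] <- 1
  Fm <- solve(B, U)
  mean(vapply(1:3, function(ax) sum(Fm[seq(ax, 3 * n, by = 3), ax]),
              numeric(1)))
}

#' Bead-model sedimentation coefficients
#'
#' Computes the anhydrous sedimentation coefficient of a bead model from its
#' translational friction, `s_anh = M (1 - vbar rho) / (N_A f_t)`, and the
#' hydrated equivalent `s_hyd = F * s_anh` with the hydration conversion
#' factor `F` from [hydration_factor()] evaluated at the particle's
#' hydration `params$delta1` and the solvent specific volume.
#'
#' @param model a [bead_model()].
#' @param params a [molecular_params()] (mass, vbar, hydration).
#' @param solvent a [solvent_conditions()].
#' @param method friction method, see [bead_friction()].
#' @return list with `s_anh`, `s_hyd` (Svedberg), `F`, `f_t` (g/s).
#' @export
model_sedimentation <- function(model, params, solvent = water20(),
                                method = "supermatrix") {
  stopifnot(inherits(params, "molecular_params"))
  buoy <- 1 - params$vbar * solvent$rho
  if (buoy <= 0) stop("(1 - vbar*rho) <= 0: particle would float")
  f_t <- bead_friction(model, solvent, method = method)
  s_anh <- params$M * buoy / (.N_A * f_t) / .SVEDBERG
  F <- hydration_factor(params$vbar, params$delta1, solvent$v1_0)
  list(s_anh = s_anh, s_hyd = F * s_anh, F = F, f_t = f_t)
}
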