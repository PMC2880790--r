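#' Anhydrous equivalent-sphere radius
#'
#' Radius of the anhydrous sphere with the particle's mass and partial
#' specific volume: `R0 = (3 M vbar / (4 pi N_A))^(1/3)`, in Angstrom.
#'
#' @param params a [molecular_params()].
#' @return R0 in Angstrom.
#' @examples
#' anhydrous_radius(molecular_params(3551100, 0.744))  # ~102 A
#' @export
anhydrous_radius <- function(params) {
  stopifnot(inherits(params, "molecular_params"))
  V <- params$M * params$vbar / .N_A            # cm^3
  (3 * V / (4 * pi))^(1 / 3) / .CM_PER_ANGSTROM
}

#' Svedberg-relation hydrodynamic parameters
#'
#' Derives the full single-particle hydrodynamic parameter set from mass,
#' partial specific volume and a standardized sedimentation coefficient:
#' translational friction `f = M (1 - vbar rho) / (N_A s)`, Stokes radius
#' `Rs = f / (6 pi eta)`, Stokes diameter `Ds = 2 Rs`, translational
#' diffusion coefficient `Dt = kB T / f`, anhydrous-sphere radius `R0` and
#' friction `f0 = 6 pi eta R0`, and the frictional ratio `f/f0`
#' (equivalently the ratio of the anhydrous sphere's sedimentation
#' coefficient to the measured one).
#'
#' @param params a [molecular_params()].
#' @param s20w0 sedimentation coefficient (Svedberg), standardized and
#'   extrapolated to infinite dilution.
#' @param solvent a [solvent_conditions()]; default standard water at 20 C.
#' @return An object of class `hydro_result` with elements `M`, `vbar`,
#'   `s20w0`, `R0` (A), `f` (g/s), `f0` (g/s), `f_over_f0`, `Rs` (A),
#'   `Ds` (A), `Dt` (cm^2/s).
#' @examples
#' svedberg_params(molecular_params(1671348, 0.746), 27.5)
#' @export
svedberg_params <- function(params, s20w0, solvent = water20()) {
  stopifnot(inherits(params, "molecular_params"),
            inherits(solvent, "solvent_conditions"), s20w0 > 0)
  s20w0 <- unname(s20w0)
  buoy <- 1 - params$vbar * solvent$rho
  if (buoy <= 0)
    stop("(1 - vbar*rho) <= 0: particle would float in this solvent")
  s_sec <- s20w0 * .SVEDBERG
  f <- params$M * buoy / (.N_A * s_sec)         # g/s
  Rs_cm <- f / (6 * pi * solvent$eta)
  R0 <- anhydrous_radius(params)                 # A
  f0 <- 6 * pi * solvent$eta * R0 * .CM_PER_ANGSTROM
  structure(list(M = params$M, vbar = params$vbar, s20w0 = s20w0,
                 R0 = R0, f = f, f0 = f0, f_over_f0 = f / f0,
                 Rs = Rs_cm / .CM_PER_ANGSTROM,
                 Ds = 2 * Rs_cm / .CM_PER_ANGSTROM,
                 Dt = .k_B * solvent$T / f),
            class = "hydro_result")
}

#' @export
print.hydro_result <- function(x, ...) {
  cat("Svedberg-derived hydrodynamic parameters\n")
  cat(sprintf("  M = %s Da, vbar = %.3f mL/g, s20,w0 = %.2f S\n",
              format(x$M, big.mark = ","), x$vbar, x$s20w0))
  cat(sprintf("  R0 = %.1f A   Rs = %.1f A   Ds = %.1f A (%.1f nm)\n",
              x$R0, x$Rs, x$Ds, x$Ds / 10))
  cat(sprintf("  f = %.3e g/s   f/f0 = %.2f   Dt = %.3e cm^2/s\n",
              x$f, x$f_over_f0, x$Dt))
  if (!is.null(x$F_hydr))
    cat(sprintf("  bead model: s_anh = %.2f S, F = %.3f, s_hyd = %.2f S\n",
                x$s_anh, x$F_hydr, x$s_hyd))
  invisible(x)
}

#' Standardize a sedimentation coefficient to water at 20 C
#'
#' Applies the usual viscosity and buoyancy correction
#' `s20,w = s_obs * (eta_exp / eta_20,w) * ((1 - vbar rho)_20,w /
#' (1 - vbar rho)_exp)`.
#'
#' @param s_obs observed sedimentation coefficient (Svedberg).
#' @param experimental a [solvent_conditions()] describing the experiment.
#' @param vbar partial specific volume (mL/g).
#' @param standard reference conditions (default water at 20 C).
#' @return s20,w in Svedberg.
#' @export
standardize_s <- function(s_obs, experimental, vbar, standard = water20()) {
  stopifnot(inherits(experimental, "solvent_conditions"), s_obs > 0, vbar > 0)
  b_exp <- 1 - vbar * experimental$rho
  b_std <- 1 - vbar * standard$rho
  if (b_exp <= 0 || b_std <= 0)
    stop("(1 - vbar*rho) <= 0: particle would float")
  s_obs * (experimental$eta / standard$eta) * (b_std / b_exp)
}

#' Extrapolate sedimentation coefficients to infinite dilution
#'
#' Weighted linear fit of `s` versus concentration; the intercept is the
#' concentration-independent `s0`. A reciprocal fit (`1/s` versus `c`) is
#' available behind `reciprocal = TRUE`. A single point is returned as-is
#' with infinite standard error and a warning.
#'
#' @param concentrations loading concentrations (any consistent unit).
#' @param s_values sedimentation coefficients (Svedberg).
#' @param errors optional standard errors of `s_values` (used as weights).
#' @param reciprocal fit `1/s` vs `c` instead of `s` vs `c`.
#' @return list with `s0`, `stderr`, `slope`, `fit` (the `lm` object or NULL).
#' @export
extrapolate_s0 <- function(concentrations, s_values, errors = NULL,
                           reciprocal = FALSE) {
  stopifnot(length(concentrations) == length(s_values))
  if (length(s_values) < 2L) {
    warning("single concentration point: returning it unchanged with infinite stderr")
    return(list(s0 = s_values, stderr = Inf, slope = NA_real_, fit = NULL))
  }
  w <- if (is.null(errors)) rep(1, length(s_values)) else 1 / errors^2
  y <- if (reciprocal) 1 / s_values else s_values
  fit <- stats::lm(y ~ concentrations, weights = w)
  # noise-free data fit exactly; the perfect-fit warning is benign
  sm <- suppressWarnings(summary(fit)$coefficients)
  if (reciprocal) {
    inv0 <- sm[1, 1]
    if (inv0 <= 0) stop("non-positive 1/s intercept: unphysical extrapolation")
    list(s0 = 1 / inv0, stderr = sm[1, 2] / inv0^2, slope = sm[2, 1], fit = fit)
  } else {
    list(s0 = sm[1, 1], stderr = sm[1, 2], slope = sm[2, 1], fit = fit)
  }
}

#' Hydration conversion factor
#'
#' The multiplicative factor converting an anhydrous computed sedimentation
#' coefficient into its hydrated equivalent:
#' `F = (vbar / (vbar + delta1 * v1_0))^(1/3)`, with `delta1` the hydration
#' (g water per g protein) and `v1_0` the specific volume of the solvent.
#' For a typical protein (`vbar ~ 0.745`, `delta1 = 0.4` g/g, water) F is
#' about 0.87.
#'
#' @param vbar partial specific volume (mL/g).
#' @param delta1 hydration (g water / g protein).
#' @param v1_0 solvent specific volume (mL/g).
#' @return F, dimensionless in (0, 1].
#' @examples
#' hydration_factor(0.744, 0.4, 1.002)   # ~0.87
#' @export
hydration_factor <- function(vbar, delta1 = 0.4, v1_0 = 1.002) {
  stopifnot(vbar > 0, delta1 >= 0, v1_0 > 0)
  (vbar / (vbar + delta1 * v1_0))^(1 / 3)
}
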