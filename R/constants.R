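# Physical constants (CODATA 2018), cgs internally; interfaces use
# Angstrom / Svedberg / Dalton / degrees-Kelvin.
.N_A <- 6.02214076e23          # mol^-1
.k_B <- 1.380649e-16           # erg/K
.R_GAS <- 8.314462618e7        # erg mol^-1 K^-1
.R_GAS_SI <- 8.314462618      # J mol^-1 K^-1
.CM_PER_ANGSTROM <- 1e-8
.SVEDBERG <- 1e-13             # s

# restore RNG state after seeded sections so callers' streams are untouched
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric 'seed' is required", call. = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Solvent conditions
#'
#' Container for the solvent state used in sedimentation and friction
#' calculations. The default is the standard reference state: pure water at
#' 20 degrees C (density 0.99823 g/mL, viscosity 0.01002 poise).
#'
#' @param T temperature (K).
#' @param rho solvent density (g/mL).
#' @param eta solvent viscosity (poise).
#' @param v1_0 solvent specific volume (mL/g); defaults to `1/rho`.
#'
#' @return An object of class `solvent_conditions`.
#' @examples
#' water20()
#' solvent_conditions(T = 277.15, rho = 0.99997, eta = 0.01567)
#' @export
solvent_conditions <- function(T = 293.15, rho = 0.99823, eta = 0.01002,
                               v1_0 = 1 / rho) {
  stopifnot(T > 0, rho > 0, eta > 0, v1_0 > 0)
  structure(list(T = T, rho = rho, eta = eta, v1_0 = v1_0),
            class = "solvent_conditions")
}

#' @rdname solvent_conditions
#' @export
water20 <- function() solvent_conditions()

#' Molecular parameters
#'
#' Molar mass, partial specific volume and hydration of one assembly, the
#' inputs to all Svedberg-relation bookkeeping.
#'
#' @param M molar mass (Da).
#' @param vbar partial specific volume (mL/g). Values outside the usual
#'   protein window (0.5-1.0) trigger a warning, not an error.
#' @param delta1 hydration (g water per g protein), default 0.4.
#'
#' @return An object of class `molecular_params`.
#' @examples
#' molecular_params(M = 1671348, vbar = 0.746)
#' @export
molecular_params <- function(M, vbar, delta1 = 0.4) {
  M <- unname(M); vbar <- unname(vbar); delta1 <- unname(delta1)
  stopifnot(M > 0, vbar > 0, delta1 >= 0)
  if (vbar <= 0.5 || vbar >= 1.0)
    warning("vbar = ", vbar, " mL/g is outside the usual protein range (0.5-1.0)")
  structure(list(M = M, vbar = vbar, delta1 = delta1),
            class = "molecular_params")
}
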