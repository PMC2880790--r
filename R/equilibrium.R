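#' Simulate a sedimentation-equilibrium radial profile
#'
#' Generates an equilibrium concentration profile for a mixture of ideal,
#' non-interacting species: `signal(r) = baseline + sum_i a_i *
#' exp(sigma_i * (r^2 - r_ref^2) / 2)` with the reduced buoyant molar mass
#' `sigma_i = M_i (1 - vbar_i rho) omega^2 / (R T)` (cm^-2). Gaussian
#' optical noise of standard deviation `noise_sd` is added with the given
#' seed; the simulation is deterministic per seed.
#'
#' @param species list of species, each a list/vector with `M` (Da), `vbar`
#'   (mL/g) and `amplitude` (signal units at `r_ref`).
#' @param omega rotor angular velocity (rad/s); see [rpm_to_omega()].
#' @param T temperature (K).
#' @param rho solvent density (g/mL).
#' @param r_grid radial positions (cm, increasing, within 5.8-7.3 cm).
#' @param r_ref reference radius (cm); default first grid point.
#' @param baseline constant signal offset.
#' @param noise_sd Gaussian noise standard deviation (signal units).
#' @param seed integer seed (required when `noise_sd > 0`).
#' @return An object of class `se_dataset`: `r`, `signal`, `omega`, `T`,
#'   `rho`, `r_ref`, `baseline_true`.
#' @examples
#' ds <- simulate_se(list(c(M = 1.65e6, vbar = 0.746, amplitude = 0.3)),
#'                   omega = rpm_to_omega(3000), T = 277.15, rho = 1.0,
#'                   r_grid = seq(6.8, 7.25, by = 0.005))
#' @export
simulate_se <- function(species, omega, T, rho,
                        r_grid = seq(6.8, 7.25, by = 0.002),
                        r_ref = r_grid[1], baseline = 0,
                        noise_sd = 0, seed = NULL) {
  stopifnot(omega > 0, T > 0, rho > 0, length(r_grid) >= 2)
  if (any(diff(r_grid) <= 0)) stop("r_grid must be increasing")
  if (any(r_grid < 5.8 | r_grid > 7.3))
    stop("r_grid outside the plausible cell window (5.8-7.3 cm)")
  x <- (r_grid^2 - r_ref^2) / 2
  signal <- rep(baseline, length(r_grid))
  for (sp in species) {
    sp <- as.list(sp)
    if (1 - sp$vbar * rho <= 0)
      stop("(1 - vbar*rho) <= 0 for a species: it would float")
    sig <- se_sigma(sp$M, sp$vbar, omega, T, rho)
    signal <- signal + sp$amplitude * exp(sig * x)
  }
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    signal <- signal + with_seed(seed, stats::rnorm(length(signal), 0, noise_sd))
  }
  structure(list(r = r_grid, signal = signal, omega = omega, T = T,
                 rho = rho, r_ref = r_ref, baseline_true = baseline),
            class = "se_dataset")
}

#' @rdname simulate_se
#' @param rpm rotor speed in revolutions per minute.
#' @export
rpm_to_omega <- function(rpm) rpm * 2 * pi / 60

# reduced buoyant molar mass (cm^-2)
se_sigma <- function(M, vbar, omega, T, rho) {
  M * (1 - vbar * rho) * omega^2 / (.R_GAS * T)
}

# initial estimates (M_lo, M_hi, a1, b) from the log-derivative of a
# block-averaged profile; the derivative removes the unknown baseline
se_derivative_seeds <- function(x, y, k, n_blocks = 25L) {
  nb <- min(n_blocks, length(x) %/% 4L)
  idx <- cut(seq_along(x), nb, labels = FALSE)
  xb <- as.numeric(tapply(x, idx, mean))
  yb <- as.numeric(tapply(y, idx, mean))
  dy <- diff(yb) / diff(xb)
  xm <- (xb[-1] + xb[-nb]) / 2
  ok <- is.finite(dy) & dy > 0
  slope_of <- function(sel) {
    sel <- sel & ok
    if (sum(sel) < 3) return(NA_real_)
    stats::coef(stats::lm(log(dy[sel]) ~ xm[sel]))[2]
  }
  s_lo <- slope_of(xm <= stats::quantile(xm, 1 / 3))
  s_hi <- slope_of(xm >= stats::quantile(xm, 2 / 3))
  fallback <- max((log(max(yb) - min(yb) + 1e-12) -
                   log(1e-2 * (max(yb) - min(yb)) + 1e-12)) /
                    (max(x) - min(x) + 1e-12), 1e-3)
  if (!is.finite(s_lo) || s_lo <= 0) s_lo <- fallback
  if (!is.finite(s_hi) || s_hi <= 0) s_hi <- s_lo
  i0 <- which(ok)[1]
  a1 <- if (length(i0))
    max(dy[i0] / s_lo * exp(-s_lo * xm[i0]), 1e-8) else max(y[1], 1e-8)
  list(M_lo = max(s_lo / k, 1e4), M_hi = max(s_hi / k, 1e4),
       a1 = a1, b = y[1] - a1)
}

#' Fit discrete-species models to an equilibrium profile
#'
#' Nonlinear least squares of a 1- or 2-species ideal sedimentation
#' equilibrium model (shared baseline, per-species amplitude and molar
#' mass). Initial masses come from the log slope of the profile's radial
#' derivative (which cancels the unknown baseline), evaluated on the lower
#' and upper thirds of the cell; the second species is additionally
#' multi-started at 2x and 4x the first. The best converged fit over all
#' starts is kept. The single-species fit reports the apparent mass `Mapp`.
#'
#' @param dataset an `se_dataset` (from [simulate_se()] or [read_se_csv()]).
#' @param vbar partial specific volume (mL/g), shared by all species.
#' @param rho solvent density (g/mL); defaults to the dataset's.
#' @param n_species 1 or 2.
#' @return An object of class `species_fit`: data frame `species` (columns
#'   `M`, `amplitude`, `fraction`), `baseline`, `rms`, `Mapp` (single
#'   species only), and the underlying `nls` fit.
#' @export
fit_se <- function(dataset, vbar, rho = dataset$rho, n_species = 1) {
  stopifnot(inherits(dataset, "se_dataset"), n_species %in% c(1, 2))
  x <- (dataset$r^2 - dataset$r_ref^2) / 2
  y <- dataset$signal
  k <- dataset$omega^2 * (1 - vbar * rho) / (.R_GAS * dataset$T)  # sigma = k*M
  if (k <= 0) stop("(1 - vbar*rho) <= 0: species would float")

  # seeds from the log-derivative of a block-averaged profile: the
  # derivative of b + a e^(sigma x) is baseline-free, so its log slope on
  # the lower third (species-1-dominated) gives sigma_1 directly, and on
  # the upper third a value biased toward any heavier species
  sd_ <- se_derivative_seeds(x, y, k)
  df <- data.frame(x = x, y = y)
  fits <- list()
  if (n_species == 1) {
    starts <- list(
      list(b = sd_$b, a1 = sd_$a1, M1 = sd_$M_lo),
      list(b = min(y), a1 = max(y[1] - min(y), 1e-6), M1 = sd_$M_hi),
      list(b = 0, a1 = max(y[1], 1e-6), M1 = sd_$M_lo))
    form <- y ~ b + a1 * exp(k * M1 * x)
    lower <- c(b = -Inf, a1 = 0, M1 = 1e3)
  } else {
    # second species multi-started at 2x and 4x the first and at the
    # upper-third derivative estimate; its amplitude seeded to carry the
    # top-of-cell residual left by species 1
    a2_seed <- function(M2) {
      res_top <- max(utils::tail(y, 3)) -
        (sd_$b + sd_$a1 * exp(k * sd_$M_lo * max(x)))
      max(res_top, 1e-4 * diff(range(y))) / exp(k * M2 * max(x))
    }
    # the derivative estimate of M1 is biased upward when the heavy
    # species is abundant, so M1 is also multi-started below it
    grid <- expand.grid(M1f = c(1, 0.7, 0.5), M2m = c(2, 4))
    starts <- lapply(seq_len(nrow(grid)), function(i) {
      M1 <- grid$M1f[i] * sd_$M_lo
      list(b = sd_$b, a1 = sd_$a1, M1 = M1,
           a2 = a2_seed(grid$M2m[i] * M1), M2 = grid$M2m[i] * M1)
    })
    starts <- c(starts, list(
      list(b = sd_$b, a1 = sd_$a1, M1 = sd_$M_lo,
           a2 = a2_seed(2 * sd_$M_hi), M2 = max(2 * sd_$M_hi,
                                                1.2 * sd_$M_lo))))
    form <- y ~ b + a1 * exp(k * M1 * x) + a2 * exp(k * M2 * x)
    lower <- c(b = -Inf, a1 = 0, M1 = 1e3, a2 = 0, M2 = 1e3)
  }
  for (st in starts) {
    ft <- tryCatch(
      minpack.lm::nlsLM(form, data = df, start = st, lower = lower,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(ft)) fits[[length(fits) + 1L]] <- ft
  }
  if (length(fits) == 0L)
    stop("sedimentation-equilibrium fit failed to converge from all starts")
  ssr <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  fit <- fits[[which.min(ssr)]]
  cf <- stats::coef(fit)

  if (n_species == 1) {
    species <- data.frame(M = cf["M1"], amplitude = cf["a1"], fraction = 1)
  } else {
    amps <- c(cf["a1"], cf["a2"])
    Ms <- c(cf["M1"], cf["M2"])
    o <- order(amps, decreasing = TRUE)
    species <- data.frame(M = Ms[o], amplitude = amps[o],
                          fraction = amps[o] / sum(amps))
  }
  rownames(species) <- NULL
  structure(list(species = species, baseline = unname(cf["b"]),
                 rms = sqrt(mean(stats::resid(fit)^2)),
                 Mapp = if (n_species == 1) unname(cf["M1"]) else NA_real_,
                 fit = fit),
            class = "species_fit")
}

#' @export
print.species_fit <- function(x, ...) {
  cat("Sedimentation-equilibrium species fit\n")
  sp <- x$species
  for (i in seq_len(nrow(sp)))
    cat(sprintf("  species %d: M = %.4g Da, amplitude = %.4g (%.1f%% of signal)\n",
                i, sp$M[i], sp$amplitude[i], 100 * sp$fraction[i]))
  cat(sprintf("  baseline = %.4g, rms residual = %.3g\n", x$baseline, x$rms))
  invisible(x)
}

#' Infinite-dilution mass extrapolation
#'
#' Linear fit of `1/Mapp` against loading concentration; the
#' concentration-independent mass is `Mw0 = 1/intercept`, with first-order
#' error propagation of the intercept's standard error.
#'
#' @param concentrations loading concentrations.
#' @param Mapp_values apparent masses (Da) at each concentration.
#' @return list with `Mw0` (Da), `stderr`, `slope`, `fit`.
#' @examples
#' extrapolate_Mw0(c(0.2, 0.4, 0.8), rep(1.65e6, 3))
#' @export
extrapolate_Mw0 <- function(concentrations, Mapp_values) {
  stopifnot(length(concentrations) == length(Mapp_values),
            length(Mapp_values) >= 2)
  fit <- stats::lm(I(1 / Mapp_values) ~ concentrations)
  # noise-free data fit exactly; the perfect-fit warning is benign
  sm <- suppressWarnings(summary(fit)$coefficients)
  inv0 <- sm[1, 1]
  if (inv0 <= 0) stop("non-positive 1/Mapp intercept: unphysical extrapolation")
  list(Mw0 = 1 / inv0, stderr = sm[1, 2] / inv0^2, slope = sm[2, 1], fit = fit)
}
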