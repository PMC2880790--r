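#' Two-state linear-extrapolation unfolding signal
#'
#' Evaluates the standard two-state chemical denaturation model with linear
#' baselines: `dG(c) = dG0 - m * c`, unfolded fraction
#' `fU = exp(-dG/RT) / (1 + exp(-dG/RT))`, observed signal
#' `y = (1 - fU) (aN + bN c) + fU (aU + bU c)`. The midpoint is
#' `Cm = dG0 / m`, where `fU = 0.5` exactly.
#'
#' @param c denaturant concentrations (M).
#' @param dG0 Gibbs free energy of unfolding at zero denaturant (kJ/mol).
#' @param m_value dependence of dG on concentration (kJ/mol/M, > 0).
#' @param baselines numeric of length 4: `aN`, `bN`, `aU`, `bU` (native and
#'   unfolded baseline intercepts and slopes).
#' @param T temperature (K), default 298.15.
#' @return Signal values, same length as `c`.
#' @examples
#' two_state_signal(2.70, dG0 = 17.0, m_value = 17.0 / 2.70)  # midpoint
#' @export
two_state_signal <- function(c, dG0, m_value, baselines = c(1, 0, 0, 0),
                             T = 298.15) {
  stopifnot(T > 0, length(baselines) == 4)
  fU <- unfolded_fraction(c, dG0, m_value, T)
  (1 - fU) * (baselines[1] + baselines[2] * c) +
    fU * (baselines[3] + baselines[4] * c)
}

unfolded_fraction <- function(c, dG0, m_value, T) {
  dG <- (dG0 - m_value * c) * 1000           # J/mol
  stats::plogis(-dG / (.R_GAS_SI * T))
}

#' Simulate a chemical-denaturation curve
#'
#' [two_state_signal()] plus Gaussian noise, packaged as an
#' `unfolding_curve` (fields `c`, `y`, `channel`).
#'
#' @inheritParams two_state_signal
#' @param noise_sd Gaussian noise sd, in units of the total signal change
#'   between the baselines at the midpoint times `relative` (see below).
#' @param relative if TRUE (default) `noise_sd` is relative to the dynamic
#'   range; if FALSE it is in absolute signal units.
#' @param seed integer seed (required when `noise_sd > 0`).
#' @param channel label for the observable.
#' @return An object of class `unfolding_curve`.
#' @export
simulate_unfolding <- function(c, dG0, m_value, baselines = c(1, 0, 0, 0),
                               T = 298.15, noise_sd = 0, relative = TRUE,
                               seed = NULL, channel = "signal") {
  y <- two_state_signal(c, dG0, m_value, baselines, T)
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required when noise_sd > 0")
    Cm <- dG0 / m_value
    span <- abs((baselines[3] + baselines[4] * Cm) -
                (baselines[1] + baselines[2] * Cm))
    sd_abs <- if (relative) noise_sd * span else noise_sd
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, sd_abs))
  }
  unfolding_curve(c, y, channel)
}

#' @rdname simulate_unfolding
#' @param y signal values.
#' @export
unfolding_curve <- function(c, y, channel = "signal") {
  stopifnot(length(c) == length(y))
  if (any(c < 0)) stop("denaturant concentrations must be >= 0")
  if (any(diff(c) <= 0)) stop("concentrations must be strictly increasing")
  structure(list(c = as.numeric(c), y = as.numeric(y), channel = channel),
            class = "unfolding_curve")
}

#' Fit the two-state linear-extrapolation model
#'
#' Nonlinear least squares over the six parameters (dG0, m, and the four
#' baseline coefficients) with multi-start over candidate midpoints. Reports
#' `dG0` (kJ/mol), `m_value` (kJ/mol/M), `Cm = dG0/m_value` (M) and
#' parameter standard errors. Curves with no resolvable transition (flat
#' data) are rejected with an error.
#'
#' @param curve an [unfolding_curve()] with at least 6 points spanning both
#'   baselines.
#' @param T temperature (K).
#' @return An object of class `two_state_fit`: `dG0`, `m_value`, `Cm`,
#'   `baselines`, `stderr` (named vector), `rms`, `fit`.
#' @export
fit_two_state <- function(curve, T = 298.15) {
  stopifnot(inherits(curve, "unfolding_curve"))
  c <- curve$c; y <- curve$y
  if (length(c) < 6) stop("need at least 6 points spanning both baselines")
  span <- diff(range(y))
  if (span == 0) stop("no transition: zero dynamic range")
  ne <- max(2L, length(c) %/% 5L)
  yN <- mean(utils::head(y, ne)); yU <- mean(utils::tail(y, ne))
  resid_sd <- stats::sd(diff(y)) / sqrt(2)
  if (abs(yU - yN) < 4 * resid_sd / sqrt(ne))
    stop("no transition detected: endpoint plateaus are indistinguishable")

  df <- data.frame(c = c, y = y)
  RT <- .R_GAS_SI * T / 1000   # kJ/mol
  form <- y ~ (aN + bN * c) +
    (aU + bU * c - aN - bN * c) / (1 + exp((dG0 - m * c) / RT))
  Cm_starts <- stats::quantile(c, c(0.3, 0.5, 0.7))
  # crude fU from endpoint plateaus seeds m via logistic steepness
  fits <- list()
  for (Cm0 in Cm_starts) {
    for (m0 in c(3, 8, 20)) {
      st <- list(aN = yN, bN = 0, aU = yU, bU = 0, dG0 = m0 * Cm0, m = m0)
      ft <- tryCatch(
        minpack.lm::nlsLM(form, data = df, start = st,
                          lower = c(-Inf, -Inf, -Inf, -Inf, 0.01, 0.01),
                          control = minpack.lm::nls.lm.control(maxiter = 300)),
        error = function(e) NULL)
      if (!is.null(ft)) fits[[length(fits) + 1L]] <- ft
    }
  }
  if (length(fits) == 0L) stop("two-state fit failed to converge from all starts")
  ssr <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  fit <- fits[[which.min(ssr)]]
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, 2], error = function(e)
    stats::setNames(rep(NA_real_, length(cf)), names(cf)))
  structure(list(dG0 = unname(cf["dG0"]), m_value = unname(cf["m"]),
                 Cm = unname(cf["dG0"] / cf["m"]),
                 baselines = unname(cf[c("aN", "bN", "aU", "bU")]),
                 stderr = se, rms = sqrt(mean(stats::resid(fit)^2)),
                 T = T, fit = fit),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf("Two-state unfolding fit: dG0 = %.2f kJ/mol, m = %.2f kJ/mol/M, Cm = %.3f M\n",
              x$dG0, x$m_value, x$Cm))
  cat(sprintf("  baselines: native %.3g + %.3g c, unfolded %.3g + %.3g c; rms = %.3g\n",
              x$baselines[1], x$baselines[2], x$baselines[3], x$baselines[4],
              x$rms))
  invisible(x)
}

#' Percent-change normalization of an unfolding curve
#'
#' Maps the signal onto the 0-100% unfolded scale:
#' `y_norm = 100 (y - yN(c)) / (yU(c) - yN(c))` with the native and unfolded
#' baselines either taken from a two-state fit (`method = "fit"`, default)
#' or from the first/last points (`method = "endpoints"`). Out-of-range
#' values are reported as-is (no silent clamping).
#'
#' @param curve an [unfolding_curve()].
#' @param method `"fit"` or `"endpoints"`.
#' @param T temperature (K), used by the fit method.
#' @return An `unfolding_curve` on the percent scale (channel suffixed
#'   `"_pct"`).
#' @export
percent_change <- function(curve, method = c("fit", "endpoints"), T = 298.15) {
  method <- match.arg(method)
  stopifnot(inherits(curve, "unfolding_curve"))
  c <- curve$c; y <- curve$y
  if (method == "fit") {
    ft <- fit_two_state(curve, T)
    bl <- ft$baselines
    yN <- bl[1] + bl[2] * c
    yU <- bl[3] + bl[4] * c
  } else {
    ne <- max(2L, length(c) %/% 5L)
    yN <- rep(mean(utils::head(y, ne)), length(c))
    yU <- rep(mean(utils::tail(y, ne)), length(c))
  }
  dyn <- yU - yN
  if (any(abs(dyn) < .Machine$double.eps * 100))
    stop("zero dynamic range between baselines")
  unfolding_curve(c, 100 * (y - yN) / dyn,
                  channel = paste0(curve$channel, "_pct"))
}

#' Emission peak-shift metric
#'
#' For a series of fluorescence emission spectra recorded at increasing
#' denaturant concentrations, returns the per-concentration peak wavelength
#' (discrete maximum refined by a parabola through the three points around
#' it) and the barycentric mean wavelength. Spectra with multiple comparable
#' maxima have their peak flagged (`peak_flag`); the barycentre is always
#' returned.
#'
#' @param wavelength common wavelength grid (nm).
#' @param intensities matrix (length(wavelength) x n_spectra) of intensities.
#' @param c denaturant concentration per spectrum (M).
#' @return A data frame with columns `c`, `peak`, `barycentre`, `peak_flag`.
#' @export
emission_shift <- function(wavelength, intensities, c) {
  intensities <- as.matrix(intensities)
  stopifnot(nrow(intensities) == length(wavelength),
            ncol(intensities) == length(c))
  if (any(intensities < 0)) stop("intensities must be >= 0")
  out <- data.frame(c = c, peak = NA_real_, barycentre = NA_real_,
                    peak_flag = FALSE)
  for (k in seq_along(c)) {
    I <- intensities[, k]
    i <- which.max(I)
    peak <- wavelength[i]
    if (i > 1 && i < length(I)) {   # parabolic refinement
      y1 <- I[i - 1]; y2 <- I[i]; y3 <- I[i + 1]
      denom <- y1 - 2 * y2 + y3
      if (denom < 0) {
        h <- wavelength[i + 1] - wavelength[i]
        peak <- wavelength[i] + 0.5 * h * (y1 - y3) / denom
      }
    }
    # multi-modality: another local maximum above 80% of the global one
    locmax <- which(diff(sign(diff(I))) == -2) + 1L
    flag <- sum(I[locmax] > 0.8 * I[i]) > 1
    out$peak[k] <- peak
    out$barycentre[k] <- sum(wavelength * I) / sum(I)
    out$peak_flag[k] <- flag
  }
  out
}
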