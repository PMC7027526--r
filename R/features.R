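#' Estimate the spectral height (high-frequency plateau)
#'
#' Mean of D(f) over a high-frequency band, by default 900-1000 Hz, where the
#' spectra of all simulated substrates have plateaued.
#'
#' @param spectrum a `diffusion_spectrum` extending to the upper band edge.
#' @param band two-element band in Hz.
#' @return Spectral height D_hi in um^2/ms.
#' @export
estimate_height <- function(spectrum, band = c(900, 1000)) {
  stopifnot(inherits(spectrum, "diffusion_spectrum"))
  if (max(spectrum$f) < band[2])
    stop(sprintf("spectrum must extend to %g Hz", band[2]))
  idx <- spectrum$f >= band[1] & spectrum$f <= band[2]
  mean(spectrum$D[idx])
}

#' Estimate the spectral width (half width at half maximum)
#'
#' Lowest frequency at which D(f) crosses half the spectral height, located
#' by linear interpolation between grid points; for non-monotone spectra the
#' first upward crossing is taken.
#'
#' @param spectrum a `diffusion_spectrum`.
#' @param D_hi spectral height; estimated via [estimate_height()] if missing.
#' @return Spectral width f_Delta in Hz.
#' @export
estimate_width <- function(spectrum, D_hi = NULL) {
  stopifnot(inherits(spectrum, "diffusion_spectrum"))
  if (is.null(D_hi)) D_hi <- estimate_height(spectrum)
  if (D_hi <= 0) stop("D_hi must be > 0")
  half <- D_hi / 2
  above <- which(spectrum$D >= half)
  if (!length(above)) stop("no half-height crossing in the frequency range")
  i <- above[1]
  if (i == 1) return(spectrum$f[1])
  f0 <- spectrum$f[i - 1]; f1 <- spectrum$f[i]
  d0 <- spectrum$D[i - 1]; d1 <- spectrum$D[i]
  f0 + (half - d0) / (d1 - d0) * (f1 - f0)
}

#' Predict the spectral height from the microscopic orientation dispersion
#'
#' \eqn{D_{hi} = \mu OD \cdot D_0} for a single fiber; for an ensemble the
#' (optionally weighted) mean over members.
#'
#' @param muOD microscopic orientation dispersion(s) in \[0, 1\].
#' @param D0 bulk diffusivity, um^2/ms.
#' @param weights optional ensemble weights.
#' @return Predicted height in um^2/ms.
#' @export
predict_height <- function(muOD, D0 = 1.7, weights = NULL) {
  if (any(muOD < 0 | muOD > 1)) stop("muOD must lie in [0, 1]")
  if (length(muOD) == 1) return(muOD * D0)
  if (is.null(weights)) weights <- rep(1, length(muOD))
  sum(weights * muOD * D0) / sum(weights)
}

#' Predict the spectral width from model parameters
#'
#' Case-specific predictions with the module constants:
#' cylinders \eqn{f_\Delta = k_c D_0/d^2}; 1-harmonic fibers
#' \eqn{f_\Delta \approx k_h D_0 \mu OD / a^2}; n-harmonic ensembles the
#' height-weighted mean of member widths; stochastic fibers
#' \eqn{f_\Delta \approx k_s (D_0/a_{max}^2)\,\langle\mu OD(x)^2\rangle/
#' \langle\mu OD(x)\rangle}.
#'
#' @param case one of `"cylinder"`, `"harmonic"`, `"n_harmonic"`,
#'   `"stochastic"`.
#' @param d cylinder diameter (um), cylinder case.
#' @param a undulation amplitude (um), harmonic case.
#' @param muOD microscopic orientation dispersion, harmonic case.
#' @param members data frame with columns `a` and `muOD`, n-harmonic case.
#' @param a_max maximal deviation (um), stochastic case.
#' @param muOD_x local dispersion profile, stochastic case.
#' @param D0 bulk diffusivity, um^2/ms.
#' @param k_c,k_h,k_s proportionality constants (defaults: exact
#'   [kc_constant()], and the simulation-calibrated 0.34 and 0.13).
#' @return Predicted width in Hz.
#' @export
predict_width <- function(case = c("cylinder", "harmonic", "n_harmonic",
                                   "stochastic"),
                          d = NULL, a = NULL, muOD = NULL, members = NULL,
                          a_max = NULL, muOD_x = NULL, D0 = 1.7,
                          k_c = kc_constant(), k_h = 0.34, k_s = 0.13) {
  case <- match.arg(case)
  switch(case,
    cylinder = {
      if (is.null(d)) stop("cylinder case requires d")
      khz_to_hz(k_c * D0 / d^2)
    },
    harmonic = {
      if (is.null(a) || is.null(muOD))
        stop("harmonic case requires a and muOD")
      khz_to_hz(k_h * D0 * muOD / a^2)
    },
    n_harmonic = {
      if (is.null(members)) stop("n_harmonic case requires members")
      w <- members$muOD * D0                      # heights as weights
      fi <- khz_to_hz(k_h * D0 * members$muOD / members$a^2)
      sum(w * fi) / sum(w)
    },
    stochastic = {
      if (is.null(a_max) || is.null(muOD_x))
        stop("stochastic case requires a_max and muOD_x")
      khz_to_hz(k_s * D0 / a_max^2 * mean(muOD_x^2) / mean(muOD_x))
    })
}

#' Fit a single Lorentzian to a diffusion spectrum
#'
#' Nonlinear least squares of \eqn{L(f) = D_{hi} f^2/(f_\Delta^2 + f^2)} on
#' the spectrum's frequency grid, initialized from [estimate_height()] and
#' [estimate_width()].
#'
#' @param spectrum a `diffusion_spectrum` with at least 10 points spanning
#'   both sides of the half height.
#' @return List with `D_hi`, `f_delta` (Hz) and the `nls` fit object.
#' @export
fit_lorentzian <- function(spectrum) {
  stopifnot(inherits(spectrum, "diffusion_spectrum"))
  if (length(spectrum$f) < 10) stop("need >= 10 frequency points")
  d0 <- estimate_height(spectrum, band = c(0.9, 1) * max(spectrum$f))
  f0 <- estimate_width(spectrum, d0)
  dat <- data.frame(f = spectrum$f, D = spectrum$D)
  fit <- minpack.lm::nlsLM(D ~ Dhi * f^2 / (fd^2 + f^2), data = dat,
                           start = list(Dhi = d0, fd = f0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!fit$convInfo$isConv)
    stop("Lorentzian fit did not converge; residual sum of squares ",
         format(sum(stats::resid(fit)^2)))
  co <- coef(fit)
  list(D_hi = unname(co["Dhi"]), f_delta = abs(unname(co["fd"])), fit = fit)
}

#' Fit the low-frequency power-law exponent
#'
#' Straight-line least squares of log D(f) against log f over the
#' low-frequency region (0, min(f_Delta, `f_max_cap`)\], i.e.
#' \eqn{D(f) \approx c f^{p}}. The lowest fitted frequency is the grid
#' resolution (f = 0 is excluded).
#'
#' @param spectrum a `diffusion_spectrum`.
#' @param f_delta spectral width in Hz (estimated if missing).
#' @param f_max_cap upper cap of the fit region in Hz (default 20).
#' @return List with `p_fit` and prefactor `c`.
#' @export
fit_power_exponent <- function(spectrum, f_delta = NULL, f_max_cap = 20) {
  stopifnot(inherits(spectrum, "diffusion_spectrum"))
  if (is.null(f_delta)) f_delta <- estimate_width(spectrum)
  hi <- min(f_delta, f_max_cap)
  idx <- which(spectrum$f > 0 & spectrum$f <= hi & spectrum$D > 0)
  if (length(idx) < 4) stop("fewer than 4 grid points in the fit region")
  fit <- lm(log(D) ~ log(f), data.frame(f = spectrum$f[idx],
                                        D = spectrum$D[idx]))
  list(p_fit = unname(coef(fit)[2]), c = exp(unname(coef(fit)[1])))
}

#' Frequency-resolved power-law exponent
#'
#' Centered finite-difference slope
#' \eqn{p(f) = d\log(D(f)/D_{hi}) / d\log f}; points with non-positive D are
#' masked (NA).
#'
#' @param spectrum a `diffusion_spectrum`.
#' @return List with `f` (Hz, interior grid points) and `p`.
#' @export
derivative_exponent <- function(spectrum) {
  stopifnot(inherits(spectrum, "diffusion_spectrum"))
  f <- spectrum$f; D <- spectrum$D
  ok <- f > 0 & D > 0
  f <- f[ok]; D <- D[ok]
  n <- length(f)
  if (n < 3) stop("need at least 3 positive points")
  p <- (log(D[-(1:2)]) - log(D[1:(n - 2)])) /
    (log(f[-(1:2)]) - log(f[1:(n - 2)]))
  list(f = f[2:(n - 1)], p = p)
}

#' Calibrate a width proportionality constant on a substrate grid
#'
#' Through-origin least squares of estimated spectral widths against the
#' model predictor evaluated with k = 1 (the theory has no intercept);
#' returns the slope k and the Pearson correlation of the pairs. Warns when
#' the correlation falls below 0.9.
#'
#' @param predictors predictor values (Hz, computed with k = 1).
#' @param widths estimated spectral widths (Hz).
#' @return List with `k` and `correlation`.
#' @export
calibrate_width_constant <- function(predictors, widths) {
  if (length(predictors) < 5) stop("need at least 5 substrates")
  if (length(predictors) != length(widths)) stop("length mismatch")
  k <- sum(predictors * widths) / sum(predictors^2)
  r <- cor(predictors, widths)
  if (r < 0.9)
    warning(sprintf("width calibration correlation %.3f < 0.9", r))
  list(k = k, correlation = r)
}

#' Write a per-substrate feature table
#'
#' Tab-separated table with one row per substrate (columns `a`, `lambda`,
#' `muOD`, `D_hi_pred`, `D_hi_est`, `f_delta_pred`, `f_delta_est`, `p_fit`).
#'
#' @param features a data frame with those columns.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  write.table(features, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
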