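#' The 15-substrate 1-harmonic grid
#'
#' Amplitudes 1, 2, 3 um crossed with wavelengths 10, 20, 30, 40, 50 um.
#'
#' @param a amplitudes in um.
#' @param lambda wavelengths in um.
#' @return Data frame with columns `a` and `lambda`.
#' @export
substrate_grid <- function(a = 1:3, lambda = seq(10, 50, by = 10)) {
  expand.grid(a = a, lambda = lambda, KEEP.OUT.ATTRS = FALSE)
}

#' Microscopic orientation dispersion over the substrate grid
#'
#' Builds each 1-harmonic fiber at segment length `dl` and tabulates its
#' microscopic orientation dispersion; rows are amplitudes, columns
#' wavelengths.
#'
#' @param dl segment length in um.
#' @param a,lambda grid values in um.
#' @return Matrix of muOD values (rows: amplitudes, columns: wavelengths).
#' @export
run_table_muOD <- function(dl = 0.1, a = 1:3, lambda = seq(10, 50, by = 10)) {
  m <- matrix(NA_real_, length(a), length(lambda),
              dimnames = list(paste0("a=", a), paste0("lambda=", lambda)))
  for (i in seq_along(a)) for (j in seq_along(lambda)) {
    traj <- build_harmonic_fiber(undulation_params(a[i], lambda[j]), 1, dl)
    m[i, j] <- microscopic_orientation_dispersion(traj)
  }
  m
}

# Gaussian-sampling spectrum of one harmonic substrate, building just enough
# periods for the 6-sigma margins of the requested time grid
harmonic_spectrum <- function(a, lambda, D0 = 1.7, dl = 0.1,
                              times = default_times(),
                              f_grid = default_frequencies()) {
  params <- undulation_params(a, lambda)
  np <- periods_needed(params, D0, max(times), dl)
  traj <- build_harmonic_fiber(params, n_periods = np, dl = dl)
  msd <- gaussian_sampling_msd(traj, D0, times)
  list(traj = traj, msd = msd,
       spectrum = spectrum_from_msd(msd, f_grid),
       muOD = microscopic_orientation_dispersion(traj))
}

#' Simulate spectra and features over the 1-harmonic substrate grid
#'
#' For every grid substrate: Gaussian-sampling spectrum, estimated height
#' (900-1000 Hz average) and width (half-height crossing), predicted height
#' (muOD D0) and k = 1 width predictor (D0 muOD / a^2), low-frequency
#' power-law exponent; then calibrates the width constant k_h through the
#' origin and reports prediction/estimation correlations.
#'
#' @param D0 bulk diffusivity, um^2/ms.
#' @param dl segment length, um.
#' @param times time grid in ms.
#' @param f_grid frequency grid in Hz.
#' @param grid substrate grid (data frame with `a`, `lambda`).
#' @param verbose print one line per substrate.
#' @return List with `features` (data frame), `spectra` (list), `k_h`,
#'   `width_correlation`, `height_correlation`.
#' @export
run_spectra_grid <- function(D0 = 1.7, dl = 0.1, times = default_times(),
                             f_grid = default_frequencies(),
                             grid = substrate_grid(), verbose = FALSE) {
  n <- nrow(grid)
  feats <- data.frame(a = grid$a, lambda = grid$lambda, muOD = NA_real_,
                      D_hi_pred = NA_real_, D_hi_est = NA_real_,
                      f_delta_pred1 = NA_real_, f_delta_est = NA_real_,
                      p_fit = NA_real_)
  spectra <- vector("list", n)
  for (i in seq_len(n)) {
    hs <- harmonic_spectrum(grid$a[i], grid$lambda[i], D0, dl, times, f_grid)
    spectra[[i]] <- hs$spectrum
    dhi <- estimate_height(hs$spectrum)
    fde <- estimate_width(hs$spectrum, dhi)
    feats$muOD[i] <- hs$muOD
    feats$D_hi_pred[i] <- predict_height(hs$muOD, D0)
    feats$D_hi_est[i] <- dhi
    feats$f_delta_pred1[i] <- khz_to_hz(D0 * hs$muOD / grid$a[i]^2)  # k = 1
    feats$f_delta_est[i] <- fde
    feats$p_fit[i] <- fit_power_exponent(hs$spectrum, f_delta = fde)$p_fit
    if (verbose)
      message(sprintf("a=%g lambda=%g: muOD=%.3f D_hi=%.3f f_delta=%.1f Hz",
                      grid$a[i], grid$lambda[i], hs$muOD, dhi, fde))
  }
  cal <- calibrate_width_constant(feats$f_delta_pred1, feats$f_delta_est)
  list(features = feats, spectra = spectra, k_h = cal$k,
       width_correlation = cal$correlation,
       height_correlation = cor(feats$D_hi_pred, feats$D_hi_est))
}

#' Single-Lorentzian adequacy of four example spectra
#'
#' Reproduces the four-way comparison of simulated against single-Lorentzian
#' spectra through their signals: a cylinder (d = 10 um), a 1-harmonic fiber
#' (a = 2, lambda = 30 um), an n-harmonic gamma ensemble, and a stochastic
#' fiber. Each simulated spectrum is fitted by a single Lorentzian; signals
#' for both are generated under the four-waveform protocol and their MSE is
#' compared with the SNR = 50 noise floor of 4e-4.
#'
#' @param D0 bulk diffusivity, um^2/ms.
#' @param t_max time-grid extent for the fiber spectra, ms.
#' @param n_fibers ensemble size of the n-harmonic example.
#' @param seed RNG seed for the ensemble and the stochastic fiber.
#' @param f_grid frequency grid in Hz.
#' @return Data frame with one row per example (`case`, `mse`,
#'   `noise_floor`); the spectra are attached as attribute `"spectra"`.
#' @export
run_lorentzian_mse <- function(D0 = 1.7, t_max = 1000, n_fibers = 24,
                               seed = 1905, f_grid = default_frequencies()) {
  times <- default_times(t_max = t_max)
  enc <- lapply(protocol_waveforms(), encoding_spectrum)
  specs <- list()
  specs$cylinder <- analytic_spectrum(restricted_geometry(2, 5, D0), f_grid)
  specs$harmonic <- harmonic_spectrum(2, 30, D0, times = times,
                                      f_grid = f_grid)$spectrum
  members <- sample_harmonic_ensemble(
    ensemble_spec(n_fibers = n_fibers, seed = seed))
  member_specs <- lapply(members, function(p)
    harmonic_spectrum(p$amplitude, p$wavelength, D0, times = times,
                      f_grid = f_grid)$spectrum)
  specs$n_harmonic <- average_spectra(member_specs)
  sp <- undulation_params(2, 30, phase_mode = "ar1")
  st_len <- max(10 * sp$wavelength, 2 * 6 * sqrt(2 * D0 * t_max) + 100)
  st <- build_stochastic_fiber(sp, total_length = st_len, seed = seed + 1)
  specs$stochastic <- spectrum_from_msd(
    gaussian_sampling_msd(st, D0, times), f_grid)
  mse <- vapply(specs, function(s) {
    lor <- fit_lorentzian(s)
    lsp <- new_diffusion_spectrum(
      s$f, lor$D_hi * s$f^2 / (lor$f_delta^2 + s$f^2), s$D0, "analytic")
    s_sim <- vapply(enc, function(e) signal_from_spectrum(s, e), numeric(1))
    s_lor <- vapply(enc, function(e) signal_from_spectrum(lsp, e), numeric(1))
    mean((s_sim - s_lor)^2)
  }, numeric(1))
  out <- data.frame(case = names(specs), mse = unname(mse),
                    noise_floor = noise_mse(50))
  attr(out, "spectra") <- specs
  out
}

#' Diameter-bias map over the 1-harmonic grid
#'
#' Generates noise-free signals for every grid substrate under the
#' four-waveform protocol, fits a straight-cylinder diameter to each, and
#' compares with the undulation-based prediction
#' \eqn{d \approx \sqrt{k_c/k_h}\, a\, \mu OD^{-1/4}}.
#'
#' @param grid_run result of [run_spectra_grid()] (its spectra are reused).
#' @param k_h width constant used in the prediction (default the grid-run
#'   calibration).
#' @return Data frame (`a`, `lambda`, `muOD`, `f_delta`, `d_est`, `d_pred`,
#'   `at_bound`).
#' @export
run_diameter_bias <- function(grid_run, k_h = grid_run$k_h) {
  enc <- lapply(protocol_waveforms(), encoding_spectrum)
  feats <- grid_run$features
  out <- feats[, c("a", "lambda", "muOD")]
  out$f_delta <- feats$f_delta_est
  out$d_est <- NA_real_; out$d_pred <- NA_real_; out$at_bound <- NA
  for (i in seq_len(nrow(feats))) {
    S <- vapply(enc, function(e)
      signal_from_spectrum(grid_run$spectra[[i]], e), numeric(1))
    fit <- fit_cylinder_diameter(S, enc)
    out$d_est[i] <- fit$d_est
    out$at_bound[i] <- fit$at_bound
    out$d_pred[i] <- taylor_predicted_diameter(feats$a[i], feats$muOD[i],
                                               k_h = k_h)
  }
  out
}
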