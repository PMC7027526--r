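test_that("PGSE waveforms refocus and carry the Stejskal-Tanner b-value", {
  wf <- pgse_waveform(57, 5, 87)
  expect_equal(wf$q[length(wf$q)], 0)
  expect_equal(wf$b, 0.50, tolerance = 0.01)
  expect_equal(wf$tau, 92)
  # printed-protocol timings give b = 2.63, 2.45, 0.50, 0.68
  b <- vapply(protocol_waveforms(), function(w) w$b, numeric(1))
  expect_equal(b, c(2.63, 2.45, 0.50, 0.68), tolerance = 0.01)
  wf0 <- pgse_waveform(0, 5, 87)
  expect_equal(encoding_spectrum(wf0)$b, 0)
  expect_error(pgse_waveform(57, 10, 5), "delta")
})

test_that("encoding spectra satisfy Parseval and the gradient integrates to zero", {
  for (wf in protocol_waveforms()) {
    e <- encoding_spectrum(wf)
    expect_lt(abs(e$b - wf$b) / wf$b, 0.01)          # freq vs closed form
    expect_lt(abs(e$b_time - wf$b) / wf$b, 0.01)     # time vs closed form
    # zero net gradient area: exact refocusing of q, staircase-sampled g
    # can only be off by a single edge sample
    expect_equal(wf$q[length(wf$q)], 0)
    expect_lte(abs(sum(wf$g) * wf$dt), wf$G * wf$dt + 1e-12)
  }
})

test_that("encoding widths of the protocol are ~6, 6, 6 and 20 Hz", {
  ed <- vapply(protocol_enc_cached(), function(e) e$e_delta, numeric(1))
  expect_true(all(ed[1:3] > 4.5 & ed[1:3] < 7.5))
  expect_lt(abs(ed[4] - 20) / 20, 0.15)
})

test_that("signal synthesis has the correct trivial and Gaussian limits", {
  f <- default_frequencies()
  enc <- protocol_enc_cached()[[1]]
  zero <- lorentzian_spectrum(0, 10)
  expect_equal(signal_from_spectrum(zero, enc), 1)
  const <- structure(list(f = f, D = rep(1.7, length(f)), D0 = 1.7,
                          provenance = "analytic"),
                     class = "diffusion_spectrum")
  expect_equal(signal_from_spectrum(const, enc),
               exp(-enc$waveform$b * 1.7), tolerance = 1e-3)
  short <- structure(list(f = seq(0, 10, 0.5), D = rep(1.7, 21), D0 = 1.7,
                          provenance = "analytic"),
                     class = "diffusion_spectrum")
  expect_error(signal_from_spectrum(short, enc), "cover")
})

test_that("phase accrual reproduces stationary and free-diffusion limits", {
  wf <- pgse_waveform(60, 13, 20, dt = 0.05)
  nt <- ceiling(wf$tau / 0.05) + 1
  still <- matrix(5, nrow = nt, ncol = 50)         # stationary particles
  expect_equal(mc_phase_signal(still, wf, dt = 0.05), 1)
  set.seed(31)
  n <- 4000
  D0 <- 1.7
  steps <- matrix(rnorm((nt - 1) * n, sd = sqrt(2 * D0 * 0.05)), nt - 1, n)
  paths <- rbind(0, apply(steps, 2, cumsum))
  S <- mc_phase_signal(paths, wf, dt = 0.05)
  expect_equal(S, exp(-wf$b * D0), tolerance = 3 * 1 / sqrt(n))
})

test_that("first-cumulant signals match phase-accrual walkers to high attenuation", {
  p <- undulation_params(2, 10)
  times <- default_times(400)
  tr <- cached("fiber_210_long", build_harmonic_fiber(
    p, n_periods = ceiling((11.5 + 12 * sqrt(2 * 1.7 * 400)) / 11.5)))
  sp <- spectrum_from_msd(gaussian_sampling_msd(tr, times = times))
  wfs <- c(protocol_waveforms()[c(1, 4)],
           list(pgse_waveform(150, 13, 20), pgse_waveform(240, 13, 20)))
  S_spec <- vapply(wfs, function(w)
    signal_from_spectrum(sp, encoding_spectrum(w)), numeric(1))
  S_mc <- mc_fiber_signal(tr, wfs, n_particles = 1.5e4, seed = 99)
  # b <= 3 regime (attenuation ~< 20%): within 1%
  expect_true(all(abs(S_mc[1:2] - S_spec[1:2]) < 0.01))
  # extended b pushing toward ~60% attenuation: still close
  expect_lt(min(S_spec), 0.75)
  expect_true(all(abs(S_mc - S_spec) < 0.02))
})

test_that("noise MSE is (1/SNR)^2 and scales accordingly", {
  expect_equal(noise_mse(50), 4e-4)
  expect_equal(noise_mse(100), 1e-4)
  expect_equal(noise_mse(5) / noise_mse(50), 100)
  expect_error(noise_mse(0), "SNR")
})

test_that("waveform files round-trip through the two-column format", {
  wf <- pgse_waveform(46, 15, 77)
  path <- tempfile()
  write_waveform(wf, path)
  wf2 <- read_waveform(path)
  expect_identical(wf$g, wf2$g)
  expect_equal(wf2$b, wf$b, tolerance = 1e-3)   # trapezoid vs closed form
  expect_equal(max(abs(wf$q - wf2$q)), 0, tolerance = 1e-12)
  unlink(path)
})
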