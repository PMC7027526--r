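# Shared small fixture: a = 1, lambda = 10 fiber with a uniform short grid
# (fast; all modes of this substrate relax within ~10 ms)
fix_110 <- function() cached("fix_110", {
  p <- undulation_params(1, 10)
  times <- seq(0, 150, by = 0.05)
  tr <- build_harmonic_fiber(p, n_periods = periods_needed_110(), dl = 0.1)
  list(traj = tr, times = times, msd = gaussian_sampling_msd(tr, times = times))
})
periods_needed_110 <- function()
  ceiling((arc_length_period(1, 10) + 12 * sqrt(2 * 1.7 * 150)) /
            arc_length_period(1, 10))

test_that("a straight fiber has identically zero transverse MSD", {
  tr <- build_harmonic_fiber(undulation_params(0, 10), 200)
  msd <- gaussian_sampling_msd(tr, times = seq(0, 50, 0.5))
  expect_true(all(msd$msd == 0))
})

test_that("Gaussian-sampling MSD has the predicted short-time slope and plateau", {
  fx <- fix_110()
  msd <- fx$msd
  muOD <- microscopic_orientation_dispersion(fx$traj)
  # short-time transverse diffusivity msd/(2t) -> muOD * D0
  expect_equal(msd$msd[2] / (2 * msd$times[2]), muOD * 1.7, tolerance = 0.02)
  # plateau equals twice the arc-length variance of y (brute-force oracle)
  expect_equal(msd$msd_infinity, 2 * arc_variance_y(fx$traj), tolerance = 0.01)
  expect_true(all(diff(msd$msd) > -1e-9 * msd$msd_infinity))
  expect_true(all(msd$msd >= 0) && msd$msd[1] == 0)
})

test_that("the transform reproduces the closed form of a single relaxation mode", {
  A <- 1.3; alpha <- 0.6
  msd <- single_mode_msd(A, alpha, default_times(400))
  f <- default_frequencies()
  sp <- spectrum_from_msd(msd, f)
  w <- 2 * pi * f / 1000
  exact <- A * alpha * w^2 / (alpha^2 + w^2)
  expect_equal(sp$D[1], 0)
  i <- f > 0
  expect_lt(max(abs(sp$D[i] - exact[i]) / exact[i]), 1e-3)
})

test_that("the two spectrum routes (parts vs finite-difference VACF) agree", {
  fx <- fix_110()
  f <- default_frequencies()
  sp1 <- spectrum_from_msd(fx$msd, f, method = "parts")
  sp2 <- spectrum_from_msd(fx$msd, f, method = "vacf")
  i <- f >= 1
  expect_lt(max(abs(sp1$D[i] - sp2$D[i]) / pmax(sp1$D[i], 1e-12)), 0.01)
})

test_that("Gaussian sampling matches the mode-decomposition oracle", {
  fx <- fix_110()
  f <- default_frequencies()
  sp <- spectrum_from_msd(fx$msd, f)
  mo <- mode_decomposition_spectrum(fx$traj, f_grid = f)
  i <- f >= 1
  expect_lt(max(abs(sp$D[i] - mo$D[i]) / pmax(mo$D[i], 1e-12)), 0.03)
  # oracle plateau is muOD * D0 (Parseval)
  muOD <- microscopic_orientation_dispersion(fx$traj)
  expect_equal(estimate_height(mo), muOD * 1.7, tolerance = 0.02)
  # spectra never exceed the plateau by more than 2%
  expect_true(all(sp$D <= muOD * 1.7 * 1.02))
  expect_equal(sp$D[1], 0)
})

test_that("frequencies beyond Nyquist are refused", {
  msd <- single_mode_msd(1, 0.5, seq(0, 100, 0.5))
  expect_error(spectrum_from_msd(msd, seq(0, 5000, 10)), "Nyquist")
})

test_that("Monte Carlo walkers agree with Gaussian sampling within sampling error", {
  fx <- fix_110()
  mc <- suppressWarnings(
    mc_thin_fiber(fx$traj, n_particles = 1e4, t_max = 100, seed = 42))
  gs <- gaussian_sampling_msd(fx$traj, times = mc$times)
  # probe times (correlated MC errors: probe-based 3 SE check, see vignette)
  probes <- unique(round(exp(seq(log(2), log(length(mc$times)),
                                 length.out = 20))))
  z <- (mc$msd[probes] - gs$msd[probes]) / mc$se[probes]
  expect_true(all(abs(z) < 3))
  zall <- (mc$msd[-1] - gs$msd[-1]) / mc$se[-1]
  expect_lt(mean(abs(zall)), 1.5)
})

test_that("a straight fiber walker diffuses freely along x and not in y", {
  tr <- build_harmonic_fiber(undulation_params(0, 10), 50)
  mc <- suppressWarnings(
    mc_thin_fiber(tr, n_particles = 3e3, t_max = 10, seed = 7))
  expect_true(all(mc$msd == 0))
  tt <- mc$times[-1]
  ratio <- mc$metadata$msd_x[-1] / (2 * 1.7 * tt)
  # 3 relative standard errors for a chi-squared mean with 3e3 draws
  expect_true(all(abs(ratio - 1) < 3 * sqrt(2 / 3e3)))
})

test_that("Monte Carlo variance shrinks as 1/n_particles", {
  tr <- build_harmonic_fiber(undulation_params(1, 10), 30)
  sizes <- c(250, 2000, 16000)
  v <- vapply(sizes, function(n) {
    reps <- vapply(1:12, function(r)
      suppressWarnings(mc_thin_fiber(tr, n_particles = n, t_max = 2,
                                     seed = 100 * n + r,
                                     save_dt = 1))$msd[3],
      numeric(1))
    var(reps)
  }, numeric(1))
  slope <- coef(lm(log(v) ~ log(sizes)))[2]
  expect_lt(abs(slope + 1), 0.5)
})

test_that("averaging spectra is a weighted mean with the predicted plateau", {
  f <- seq(0, 1000, 1)
  s1 <- lorentzian_spectrum(0.2, 10, f)
  s2 <- lorentzian_spectrum(0.4, 40, f)
  av <- average_spectra(list(s1, s2))
  expect_equal(av$D, (s1$D + s2$D) / 2)
  expect_identical(average_spectra(list(s1, s1))$D, s1$D)
  expect_equal(estimate_height(av),
               mean(c(estimate_height(s1), estimate_height(s2))),
               tolerance = 1e-10)
  aw <- average_spectra(list(s1, s2), weights = c(3, 1))
  expect_equal(aw$D, 0.75 * s1$D + 0.25 * s2$D)
  expect_error(average_spectra(list(s1, lorentzian_spectrum(0.2, 10, f[-1]))),
               "common frequency grid")
})

test_that("ensemble width approximates the height-weighted member mean", {
  # synthetic members: exact Lorentzians whose widths/heights are known
  f <- default_frequencies()
  members <- data.frame(D_hi = c(0.1, 0.3, 0.5), f_delta = c(5, 15, 40))
  specs <- Map(function(h, w) lorentzian_spectrum(h, w, f),
               members$D_hi, members$f_delta)
  av <- average_spectra(specs)
  f_avg <- estimate_width(av, estimate_height(av))
  f_pred <- sum(members$D_hi * members$f_delta) / sum(members$D_hi)
  expect_equal(f_avg, f_pred, tolerance = 0.15)
})

test_that("spectrum and msd tables round-trip bit-exactly", {
  fx <- fix_110()
  sp <- spectrum_from_msd(fx$msd, seq(0, 500, 0.5))
  p1 <- tempfile(); p2 <- tempfile()
  write_spectrum(sp, p1); write_spectrum(fx$msd, p2)
  sp2 <- read_spectrum(p1); msd2 <- read_spectrum(p2)
  expect_identical(sp$D, sp2$D)
  expect_identical(sp$f, sp2$f)
  expect_identical(fx$msd$msd, msd2$msd)
  expect_equal(fx$msd$msd_infinity, msd2$msd_infinity)
  unlink(c(p1, p2))
})
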