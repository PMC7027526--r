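#' Undulation parameters of a thin-fiber trajectory
#'
#' Bundles the geometric parameters of the undulating thin-fiber model
#' \eqn{y(x) = a \sin(2\pi x/\lambda + \phi(x))}: the undulation amplitude
#' \eqn{a}, the wavelength \eqn{\lambda}, and the behaviour of the
#' phase-modulating factor \eqn{\phi(x)} (constant, or a smoothed cumulative
#' first-order autoregressive process for stochastically undulating fibers).
#'
#' @param amplitude undulation amplitude \eqn{a} in um (>= 0).
#' @param wavelength undulation wavelength \eqn{\lambda} in um (> 0).
#' @param phase_mode `"constant"` for harmonic fibers or `"ar1"` for a
#'   stochastic phase.
#' @param constant_phase phase offset in radians (constant mode; also the
#'   baseline phase in ar1 mode).
#' @param ar1_correlation lag-one correlation \eqn{\rho} of the AR(1)
#'   innovations, in \[0, 1).
#' @param ar1_noise_scale scale (radians per segment step) applied to the
#'   standardized, cumulatively summed AR(1) sequence. Zero recovers the
#'   harmonic fiber exactly. The default 0.008 was fixed once so that the
#'   realized microscopic orientation dispersion of stochastic fibers tracks
#'   the constant-phase fiber with the same \eqn{(a, \lambda)} to within ~20%.
#' @param smoothing_width width in um of the centered moving-average filter
#'   applied to the phase sequence (suppresses unphysically sharp turns).
#'
#' @return An object of class `undulation_params`.
#' @export
undulation_params <- function(amplitude, wavelength,
                              phase_mode = c("constant", "ar1"),
                              constant_phase = 0,
                              ar1_correlation = 0.9,
                              ar1_noise_scale = 0.008,
                              smoothing_width = 0.5) {
  phase_mode <- match.arg(phase_mode)
  if (!is.finite(amplitude) || amplitude < 0)
    stop("amplitude must be finite and >= 0")
  if (!is.finite(wavelength) || wavelength <= 0)
    stop("wavelength must be finite and > 0")
  if (!is.finite(constant_phase))
    stop("constant_phase must be finite")
  if (ar1_correlation < 0 || ar1_correlation >= 1)
    stop("ar1_correlation must lie in [0, 1)")
  if (ar1_noise_scale < 0 || !is.finite(ar1_noise_scale))
    stop("ar1_noise_scale must be finite and >= 0")
  if (smoothing_width <= 0)
    stop("smoothing_width must be > 0")
  if (amplitude / wavelength > 0.3)
    warning("a/lambda > 0.3: the model is only validated for mild undulations")
  structure(list(amplitude = amplitude, wavelength = wavelength,
                 phase_mode = phase_mode, constant_phase = constant_phase,
                 ar1_correlation = ar1_correlation,
                 ar1_noise_scale = ar1_noise_scale,
                 smoothing_width = smoothing_width),
            class = "undulation_params")
}

# assemble a fiber_trajectory from equal-chord vertices
new_fiber_trajectory <- function(xy, dl, params = NULL, Lambda = NA_real_,
                                 periodic = FALSE, seed = NULL,
                                 metadata = list()) {
  x <- xy[, 1]; y <- xy[, 2]
  dx <- diff(x); dy <- diff(y)
  theta <- atan2(dy, dx)
  structure(list(x = x, y = y, dl = dl, theta = theta,
                 muOD_x = sin(theta)^2,
                 Lambda = Lambda, periodic = periodic,
                 a_max = max(abs(y - mean(y))),
                 params = params, seed = seed, metadata = metadata),
            class = "fiber_trajectory")
}

#' @export
print.fiber_trajectory <- function(x, ...) {
  cat("Undulating thin-fiber trajectory\n")
  cat(sprintf("  %d vertices, dl = %g um, arc length = %.2f um\n",
              length(x$x), x$dl, (length(x$x) - 1) * x$dl))
  if (is.finite(x$Lambda))
    cat(sprintf("  period arc length Lambda = %.3f um\n", x$Lambda))
  cat(sprintf("  muOD = %.4f, a_max = %.3f um\n",
              microscopic_orientation_dispersion(x), x$a_max))
  invisible(x)
}

# finely sampled sine curve; oversampling is relative to the segment length
fine_harmonic_curve <- function(a, lambda, phase, x_max, dl, oversample = 100) {
  dx <- dl / oversample
  x <- seq(0, x_max, by = dx)
  list(x = x, y = a * sin(2 * pi * x / lambda + phase))
}

#' Build a 1-harmonic (constant-phase) undulating thin fiber
#'
#' Samples \eqn{y(x) = a\sin(2\pi x/\lambda + \phi)} on a fine grid
#' (100x oversampled relative to `dl`) and discretizes it into straight
#' segments of equal Euclidean length `dl` by marching along the curve.
#'
#' @param params an [undulation_params()] object with `phase_mode = "constant"`.
#' @param n_periods number of undulation periods covered.
#' @param dl segment length in um (default 0.1).
#' @return A `fiber_trajectory` with vertices, segment angles, the local
#'   dispersion profile \eqn{\mu OD(x) = \sin^2\theta}, and the arc length
#'   `Lambda` of one period.
#' @export
build_harmonic_fiber <- function(params, n_periods = 1, dl = 0.1) {
  stopifnot(inherits(params, "undulation_params"))
  if (params$phase_mode != "constant")
    stop("build_harmonic_fiber requires phase_mode = 'constant'")
  if (!is.finite(dl) || dl <= 0) stop("dl must be finite and > 0")
  if (dl > params$wavelength / 20)
    stop("dl too coarse: require dl <= wavelength/20")
  if (n_periods < 1) stop("n_periods must be >= 1")
  fc <- fine_harmonic_curve(params$amplitude, params$wavelength,
                            params$constant_phase,
                            n_periods * params$wavelength, dl)
  # arc length of one period from the fine chords
  i1 <- which(fc$x <= params$wavelength)
  Lambda <- sum(sqrt(diff(fc$x[i1])^2 + diff(fc$y[i1])^2))
  xy <- resample_equal_chord(fc$x, fc$y, dl)
  new_fiber_trajectory(xy, dl, params = params, Lambda = Lambda,
                       periodic = TRUE,
                       metadata = list(n_periods = n_periods))
}

# AR(1) phase profile at x-steps of dl: innovations -> AR(1) recursion ->
# standardize -> cumulative sum -> scale -> centered moving average
ar1_phase_profile <- function(params, n_pts, dl) {
  innov <- rnorm(n_pts)
  phi_raw <- as.numeric(stats::filter(innov, params$ar1_correlation,
                                      method = "recursive"))
  z <- (phi_raw - mean(phi_raw)) / sd(phi_raw)
  z <- cumsum(z) * params$ar1_noise_scale
  k <- max(1L, round(params$smoothing_width / dl))
  if (k %% 2 == 0) k <- k + 1L
  if (k > 1) {
    half <- (k - 1L) / 2L
    zp <- c(rep(z[1], half), z, rep(z[n_pts], half))
    z <- as.numeric(stats::filter(zp, rep(1 / k, k), sides = 2))[
      (half + 1L):(half + n_pts)]
  }
  z
}

#' Build a stochastically undulating thin fiber (AR(1) phase)
#'
#' The phase-modulating factor \eqn{\phi(x)} is generated as a first-order
#' autoregressive sequence at steps of `dl`, standardized to zero mean and
#' unit variance, cumulatively summed, scaled by `ar1_noise_scale`, and
#' smoothed with a centered moving average of width `smoothing_width` before
#' being inserted into the sine model. The curve is then discretized into
#' equal-length segments exactly as in [build_harmonic_fiber()].
#'
#' @param params an [undulation_params()] object with `phase_mode = "ar1"`.
#' @param total_length longitudinal (x) extent of the fiber in um; must be at
#'   least ten wavelengths.
#' @param dl segment length in um.
#' @param seed RNG seed (required; the trajectory is reproducible given it).
#' @return A `fiber_trajectory` (non-periodic).
#' @export
build_stochastic_fiber <- function(params, total_length, dl = 0.1, seed) {
  stopifnot(inherits(params, "undulation_params"))
  if (params$phase_mode != "ar1")
    stop("build_stochastic_fiber requires phase_mode = 'ar1'")
  if (missing(seed)) stop("seed is required for stochastic fibers")
  if (total_length < 10 * params$wavelength)
    stop("total_length must be >= 10 * wavelength")
  if (dl > params$wavelength / 20)
    stop("dl too coarse: require dl <= wavelength/20")
  if (params$ar1_noise_scale == 0) {
    cp <- params; cp$phase_mode <- "constant"
    n_per <- ceiling(total_length / params$wavelength)
    return(build_harmonic_fiber(cp, n_periods = n_per, dl = dl))
  }
  with_seed(seed, {
    n_pts <- floor(total_length / dl) + 1L
    phi <- ar1_phase_profile(params, n_pts, dl)
    dx <- dl / 100
    xfine <- seq(0, total_length, by = dx)
    phi_fine <- approx(seq(0, by = dl, length.out = n_pts), phi,
                       xout = xfine, rule = 2)$y
    y <- params$amplitude *
      sin(2 * pi * xfine / params$wavelength + params$constant_phase + phi_fine)
    y <- y - mean(y)   # main fiber direction along x, no macroscopic dispersion
    xy <- resample_equal_chord(xfine, y, dl)
    new_fiber_trajectory(xy, dl, params = params, Lambda = NA_real_,
                         periodic = FALSE, seed = seed)
  })
}

#' Microscopic orientation dispersion of a fiber
#'
#' \eqn{\mu OD = \langle \sin^2\theta \rangle}, the unweighted mean of
#' \eqn{\sin^2} of the segment angles. Because all segments have equal length,
#' this is the arc-length average along the trajectory.
#'
#' @param traj a `fiber_trajectory`.
#' @return A single dimensionless value in \[0, 1\].
#' @export
microscopic_orientation_dispersion <- function(traj) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  if (length(traj$theta) < 2) stop("trajectory needs at least 2 segments")
  mean(traj$muOD_x)
}

#' Local dispersion profile and maximal deviation
#'
#' @param traj a `fiber_trajectory`.
#' @return A list with `muOD_x` (per-segment \eqn{\sin^2\theta}) and `a_max`
#'   (maximal deviation of the transverse coordinate from its mean, um).
#' @export
local_dispersion_profile <- function(traj) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  list(muOD_x = traj$muOD_x, a_max = max(abs(traj$y - mean(traj$y))))
}

#' Specification of a gamma-distributed fiber ensemble
#'
#' Amplitudes and wavelengths of an n-harmonic ensemble are drawn from
#' independent gamma distributions truncated to a validated box
#' (defaults: 1 <= a <= 3 um, 10 <= lambda <= 50 um).
#'
#' @param a_shape,a_scale gamma shape/scale of the amplitude (um).
#' @param lambda_shape,lambda_scale gamma shape/scale of the wavelength (um).
#' @param a_lo,a_hi,lambda_lo,lambda_hi truncation bounds (um).
#' @param n_fibers number of member fibers.
#' @param weights spin-density weights (unnormalized); default equal.
#' @param seed RNG seed (required for reproducible sampling).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(a_shape = 4, a_scale = 0.5,
                          lambda_shape = 4, lambda_scale = 7.5,
                          a_lo = 1, a_hi = 3, lambda_lo = 10, lambda_hi = 50,
                          n_fibers = 24, weights = NULL, seed) {
  if (missing(seed)) stop("seed is required")
  if (n_fibers < 1) stop("n_fibers must be >= 1")
  if (a_lo >= a_hi || lambda_lo >= lambda_hi) stop("invalid truncation bounds")
  if (is.null(weights)) weights <- rep(1, n_fibers)
  if (length(weights) != n_fibers || any(weights < 0))
    stop("weights must be n_fibers non-negative values")
  structure(list(a_shape = a_shape, a_scale = a_scale,
                 lambda_shape = lambda_shape, lambda_scale = lambda_scale,
                 a_lo = a_lo, a_hi = a_hi,
                 lambda_lo = lambda_lo, lambda_hi = lambda_hi,
                 n_fibers = n_fibers, weights = weights, seed = seed),
            class = "ensemble_spec")
}

#' Sample undulation parameters for an n-harmonic ensemble
#'
#' Rejection-samples (a, lambda) pairs from the truncated gamma laws of an
#' [ensemble_spec()]. Errors out if the acceptance probability of the
#' untruncated laws against the box falls below 1e-3.
#'
#' @param spec an `ensemble_spec`.
#' @return A list of [undulation_params()] objects of length `n_fibers`, with
#'   the ensemble weights attached as attribute `"weights"`.
#' @export
sample_harmonic_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  with_seed(spec$seed, {
    a_acc <- numeric(0); l_acc <- numeric(0)
    tried <- 0L
    while (length(a_acc) < spec$n_fibers) {
      m <- max(1000L, 4L * spec$n_fibers)
      a <- rgamma(m, shape = spec$a_shape, scale = spec$a_scale)
      l <- rgamma(m, shape = spec$lambda_shape, scale = spec$lambda_scale)
      ok <- a >= spec$a_lo & a <= spec$a_hi &
        l >= spec$lambda_lo & l <= spec$lambda_hi
      tried <- tried + m
      a_acc <- c(a_acc, a[ok]); l_acc <- c(l_acc, l[ok])
      if (tried >= 1e5 && length(a_acc) / tried < 1e-3)
        stop("acceptance probability < 1e-3: gamma shapes and truncation ",
             "bounds are incompatible")
    }
    out <- vector("list", spec$n_fibers)
    for (i in seq_len(spec$n_fibers))
      out[[i]] <- undulation_params(a_acc[i], l_acc[i])
    attr(out, "weights") <- spec$weights
    out
  })
}

#' Write / read a fiber trajectory as a tab-separated table
#'
#' Columns `x_um`, `y_um`, full precision, with a `#`-prefixed header block
#' carrying the generation parameters and seed. The round trip is bit-exact.
#'
#' @param traj a `fiber_trajectory`.
#' @param path file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `fiber_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "fiber_trajectory"))
  hdr <- c(sprintf("# dl= %s", format(traj$dl, digits = 17)),
           sprintf("# periodic= %d", as.integer(traj$periodic)),
           sprintf("# Lambda= %s", format(traj$Lambda, digits = 17)),
           sprintf("# seed= %s",
                   if (is.null(traj$seed)) "NA" else format(traj$seed)))
  if (!is.null(traj$params)) {
    p <- traj$params
    hdr <- c(hdr, sprintf("# %s= %s", names(unclass(p)),
                          vapply(unclass(p), format, "", digits = 17)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, "x_um\ty_um"), con)
  writeLines(sprintf("%s\t%s",
                     format(traj$x, digits = 17, scientific = FALSE),
                     format(traj$y, digits = 17, scientific = FALSE)), con)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getf <- function(key) {
    ln <- grep(paste0("^# ", key, "= "), hdr, value = TRUE)
    if (!length(ln)) return(NA)
    sub(paste0("^# ", key, "= "), "", ln[1])
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", colClasses = "numeric")
  dl <- as.numeric(getf("dl"))
  Lambda <- as.numeric(getf("Lambda"))
  seed <- suppressWarnings(as.numeric(getf("seed")))
  params <- NULL
  if (!is.na(getf("amplitude"))) {
    params <- undulation_params(
      amplitude = as.numeric(getf("amplitude")),
      wavelength = as.numeric(getf("wavelength")),
      phase_mode = getf("phase_mode"),
      constant_phase = as.numeric(getf("constant_phase")),
      ar1_correlation = as.numeric(getf("ar1_correlation")),
      ar1_noise_scale = as.numeric(getf("ar1_noise_scale")),
      smoothing_width = as.numeric(getf("smoothing_width")))
  }
  new_fiber_trajectory(cbind(tab$x_um, tab$y_um), dl, params = params,
                       Lambda = Lambda,
                       periodic = as.integer(getf("periodic")) == 1L,
                       seed = if (is.na(seed)) NULL else seed)
}

#' Periods needed for a given maximal diffusion time
#'
#' Number of undulation periods so that a central one-period start window
#' keeps a +/- 6 sigma arc-length margin at the longest requested diffusion
#' time (the coverage requirement of [gaussian_sampling_msd()]).
#'
#' @param params an [undulation_params()].
#' @param D0 bulk diffusivity, um^2/ms.
#' @param t_max longest diffusion time, ms.
#' @param dl segment length, um.
#' @return Integer number of periods.
#' @export
periods_needed <- function(params, D0 = 1.7, t_max = 2000, dl = 0.1) {
  fc <- fine_harmonic_curve(params$amplitude, params$wavelength,
                            params$constant_phase, params$wavelength, dl)
  Lambda <- sum(sqrt(diff(fc$x)^2 + diff(fc$y)^2))
  margin <- 6 * sqrt(2 * D0 * t_max)
  as.integer(ceiling((Lambda + 2 * margin) / Lambda))
}
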