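# Independent oracles used across the suite: plain quadrature on the
# continuous curve, never touching the package's discretization code.

# arc-length average of sin^2(theta) for y = a sin(2 pi x / lambda)
muOD_quadrature <- function(a, lambda) {
  num <- integrate(function(x) {
    yp <- (2 * pi * a / lambda) * cos(2 * pi * x / lambda)
    yp^2 / sqrt(1 + yp^2)
  }, 0, lambda, rel.tol = 1e-10)$value
  den <- integrate(function(x) {
    yp <- (2 * pi * a / lambda) * cos(2 * pi * x / lambda)
    sqrt(1 + yp^2)
  }, 0, lambda, rel.tol = 1e-10)$value
  num / den
}

# arc length of one undulation period by adaptive quadrature
arc_length_period <- function(a, lambda) {
  integrate(function(x) {
    yp <- (2 * pi * a / lambda) * cos(2 * pi * x / lambda)
    sqrt(1 + yp^2)
  }, 0, lambda, rel.tol = 1e-10)$value
}

# mean of a gamma(shape, scale) truncated to [lo, hi], by quadrature
trunc_gamma_mean <- function(shape, scale, lo, hi) {
  num <- integrate(function(x) x * dgamma(x, shape, scale = scale),
                   lo, hi, rel.tol = 1e-10)$value
  den <- integrate(function(x) dgamma(x, shape, scale = scale),
                   lo, hi, rel.tol = 1e-10)$value
  num / den
}

# arc-length variance of the transverse coordinate of a trajectory
# (brute-force plateau oracle: msd_infinity = 2 Var_s(y))
arc_variance_y <- function(traj) {
  y <- traj$y - mean(traj$y)
  mean(y^2)
}

# exact Lorentzian spectrum object on a grid
lorentzian_spectrum <- function(D_hi, f_delta, f = default_frequencies(),
                                D0 = 1.7) {
  structure(list(f = f, D = D_hi * f^2 / (f_delta^2 + f^2), D0 = D0,
                 provenance = "analytic"),
            class = "diffusion_spectrum")
}

# msd_curve for a single relaxation mode: msd = 2A(1 - exp(-alpha t)),
# whose spectrum is A alpha w^2/(alpha^2 + w^2) in closed form
single_mode_msd <- function(A, alpha, times, D0 = 1.7) {
  structure(list(times = times, msd = 2 * A * (1 - exp(-alpha * times)),
                 msd_infinity = 2 * A, D0 = D0, se = NULL,
                 provenance = "oracle", metadata = list()),
            class = "msd_curve")
}
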