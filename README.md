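# undufiber

Time-dependent diffusion in undulating thin fibers, and what it does to
dMRI-based axon diameter estimation.

Axon diameter mapping with diffusion MRI (ActiveAx/AxCaliber-style methods)
models axons as straight impermeable cylinders and infers the diameter from
the time dependence of the intra-axonal signal. Axons, however, undulate:
their trajectories deviate quasi-sinusoidally from a straight path with
amplitudes (~1–3 um) that often exceed the axon diameter. `undufiber`
implements a minimal biophysical model of this situation — the *undulating
thin fiber*, a spin-carrying curve `y(x) = a sin(2πx/λ + φ(x))` along which
water diffuses one-dimensionally — together with the complete analysis
chain needed to quantify the resulting diameter bias:

* **Substrates**: 1-harmonic fibers, gamma-distributed n-harmonic
  ensembles, and stochastic-phase (smoothed cumulative AR(1)) fibers,
  discretized into exactly equal-length segments (`dl` = 0.1 um);
* **Diffusion spectra** `D(f)` (the Fourier transform of the velocity
  autocorrelation function): fast Gaussian-sampling estimation along the
  fiber arc, validated by Rcpp Monte Carlo walkers (thin fiber and
  undulating-cylinder strip), plus closed-form Lorentzian-sum spectra over
  Bessel roots for planar/cylindrical/spherical restrictions;
* **Spectral features**: height `D_hi = μOD · D0` (μOD = microscopic
  orientation dispersion, the arc-length mean of sin²θ), width
  `f_Δ ≈ k_h D0 μOD / a²` for fibers vs `f_Δ = k_c D0 / d²`
  (`k_c = √(1536/7)/2π ≈ 2.36`) for cylinders, single-Lorentzian fits, and
  low-frequency power-law exponents `D(f) ∝ f^p`;
* **Encoding**: rectangular PGSE waveforms, `|q(f)|²` encoding power
  spectra, b-values, encoding widths, first-cumulant signals
  `S = exp(−∫ D(f)|q(f)|² df)`, and phase-accrual Monte Carlo signals;
* **Diameter bias**: a constrained intra-axonal radial straight-cylinder
  fit applied to fiber signals, compared against the Taylor-matched
  prediction `d ≈ √(k_c/k_h) · a · μOD^(−1/4)`.

The headline result the package reproduces: thin, effectively zero-diameter
fibers that merely undulate are fitted as cylinders of 4–10 um diameter
under a standard clinical protocol, with the bias controlled by the
undulation amplitude and μOD.

## Worked example

```r
library(undufiber)

## an undulating thin fiber: a = 2 um, lambda = 30 um
params <- undulation_params(amplitude = 2, wavelength = 30)
fiber  <- build_harmonic_fiber(params, n_periods = periods_needed(params))

## its transverse diffusion spectrum by Gaussian sampling (D0 = 1.7 um^2/ms)
msd  <- gaussian_sampling_msd(fiber, D0 = 1.7)
spec <- spectrum_from_msd(msd)

D_hi    <- estimate_height(spec)                 # 900-1000 Hz plateau
f_delta <- estimate_width(spec, D_hi)            # half-height crossing
muOD    <- microscopic_orientation_dispersion(fiber)
cat(sprintf("muOD = %.3f   D_hi = %.3f um^2/ms (predicted %.3f)   f_delta = %.1f Hz\n",
            muOD, D_hi, predict_height(muOD), f_delta))

## what a straight-cylinder model reports for this (zero-diameter!) fiber
enc <- lapply(protocol_waveforms(), encoding_spectrum)
S   <- sapply(enc, function(e) signal_from_spectrum(spec, e))
fit <- fit_cylinder_diameter(S, enc)
cat(sprintf("apparent cylinder diameter: %.1f um (Taylor prediction %.1f um)\n",
            fit$d_est, taylor_predicted_diameter(2, muOD)))
```

Output:

```
muOD = 0.079   D_hi = 0.135 um^2/ms (predicted 0.135)   f_delta = 10.9 Hz
apparent cylinder diameter: 7.9 um (Taylor prediction 9.9 um)
```

The fiber's spectral height matches the μOD·D0 prediction; its width
(~11 Hz) sits right inside the encoding band of the protocol, and the
straight-cylinder model converts the undulation into an apparent diameter
of about 8 um. The Taylor-matched prediction overshoots here because part
of the encoding power falls outside the quadratic low-frequency regime —
exactly the failure mode the bias analysis maps out.

The same machinery is wrapped in grid-level runners (`run_table_muOD()`,
`run_spectra_grid()`, `run_lorentzian_mse()`, `run_diameter_bias()`) and a
thin command-line interface (`inst/cli/undufiber.R`) with subcommands
`muod-table`, `grid`, `lorentzian`, `bias` and `encode`.

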