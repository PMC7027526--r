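---
title: "Time-dependent diffusion in undulating thin fibers: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-dependent diffusion in undulating thin fibers: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(undufiber)
```

## The model

Axon diameter mapping with diffusion MRI usually represents axons as
straight impermeable cylinders and reads the diameter off the
time-dependence of the intra-axonal signal. Real axons undulate: their
trajectories deviate quasi-sinusoidally from a straight path with
amplitudes of a micrometre or more — an order of magnitude larger than many
axon diameters. This package implements a deliberately minimal model of
that situation: the *undulating thin fiber*, a spin-carrying,
infinitesimally thin curve

$$y(x) = a \sin\!\left(\frac{2\pi x}{\lambda} + \phi(x)\right)$$

in a two-dimensional plane, along which water diffuses one-dimensionally
with bulk diffusivity $D_0$. Transverse displacements — the component that
diameter models interpret — arise purely from the geometry. Three cases are
covered: a single harmonic (constant $\phi$), ensembles of harmonics with
gamma-distributed $(a, \lambda)$, and a stochastic phase $\phi(x)$ built
from a smoothed, cumulatively summed AR(1) sequence.

All analysis happens in the frequency domain. The diffusion spectrum
$D(f)$ — the Fourier transform of the velocity autocorrelation function —
is characterized by four features: its high-frequency plateau (*spectral
height* $D_{hi}$), its half-width at half maximum (*spectral width*
$f_\Delta$), its shape (a single Lorentzian
$L(f) = D_{hi} f^2/(f_\Delta^2 + f^2)$ is usually adequate), and its
low-frequency power-law exponent $p$ in $D(f) \propto f^p$. The central
structural quantity is the microscopic orientation dispersion

$$\mu OD = \langle \sin^2 \theta \rangle,$$

the arc-length average of the squared sine of the local segment angle.
The theory then predicts $D_{hi} = \mu OD \cdot D_0$ and
$f_\Delta \approx k_h D_0\, \mu OD / a^2$ for harmonic fibers, against
$f_\Delta = k_c D_0 / d^2$ with $k_c = \sqrt{1536/7}/(2\pi) \approx 2.36$
for a cylinder of diameter $d$. Matching the low-frequency quadratic
expansions of the two spectra yields the apparent diameter that a
straight-cylinder model reports for an undulating thin fiber,

$$d \approx \sqrt{k_c / k_h}\; a\; \mu OD^{-1/4},$$

which is how undulation masquerades as diameter.

## Substrate discretization

Fibers are sampled on a fine longitudinal grid (100$\times$ oversampled
relative to the segment length) and then discretized into straight segments
of *equal Euclidean length* `dl` (default 0.1 um) by marching along the
curve: each vertex is the exact intersection of the curve with a circle of
radius `dl` around the previous vertex. We chose chord-marching over
arc-length interpolation because the model's discretization contract is on
the segment lengths themselves; the marching construction satisfies it to
machine precision while keeping every vertex on the continuous curve. At
the curvatures of the validated parameter box the chord/arc distinction
changes $\mu OD$ by well under $10^{-4}$. Segment averaging of
$\sin^2\theta$ at `dl` = 0.1 um reproduces the arc-length quadrature
integral to better than $10^{-3}$ relative.

The stochastic phase is generated at steps of `dl`: AR(1) innovations with
lag-one correlation $\rho = 0.9$ are standardized to zero mean and unit
variance, cumulatively summed (a smooth random-walk phase), scaled by
`ar1_noise_scale`, and smoothed by a centered moving average of width
0.5 um to suppress unphysically sharp turns. The scale default of 0.008
radians per step was fixed once so that the realized $\mu OD$ of stochastic
fibers tracks the constant-phase fiber with the same $(a, \lambda)$ to
within roughly 20% across the validated box; it is a generator setting, not
a fitted quantity. Gamma ensembles default to shape 4 with means
$(a, \lambda) = (2, 30)$ um, rejection-truncated to the validated box
$1 \le a \le 3$ um, $10 \le \lambda \le 50$ um, with 24 member fibers —
a desk-scale ensemble size chosen once.

## Gaussian sampling and the spectrum transform

The workhorse estimator of $\langle \Delta y^2(t) \rangle$ assumes
one-dimensional Gaussian displacement statistics along the fiber arc
("Gaussian sampling"): for each diffusion time the displacement density
along the arc is a normal with variance $2 D_0 t$, truncated at $6\sigma$
and renormalized, and the transverse second moment is accumulated over all
start segments in a central window (one undulation period for harmonic
fibers, the interior for stochastic fibers). The fiber must extend six
standard deviations beyond the window at the longest diffusion time; the
builders take an `n_periods`/`total_length` argument and
`gaussian_sampling_msd()` refuses fibers that are too short. The
convolutions are evaluated by FFT, which is what makes this route a few
hundred times faster than a random-walk simulation of equivalent precision.

The transform to $D(f)$ uses the identity (two integrations by parts of the
velocity-autocorrelation definition; the short-time singular part cancels
against the boundary term)

$$D(f) = (2\pi f)^2\, \mathrm{Re} \int_0^\infty
  \tfrac12\left[\mathrm{msd}_\infty - \mathrm{msd}(t)\right]
  e^{-i 2\pi f t}\, dt .$$

Two numerical choices matter here and both were made for accuracy at the
1 kHz end of the spectrum, where the plateau estimator lives:

* **Exact oscillatory quadrature.** The integral is computed exactly for
  the piecewise-linear interpolant of the MSD (a Filon-type rule). A plain
  trapezoidal rule is *not* interchangeable: at sampling interval $h$ it
  multiplies the spectrum by $\mathrm{sinc}^2(\pi f h)$, which at
  $h = 0.25$ ms suppresses the 900–1000 Hz plateau by about 9% — far more
  than the feature tolerances.
* **A two-resolution time grid.** Defaults: 0.04 ms steps up to 30 ms
  (resolving the fast relaxation modes that carry the high-frequency
  content), then 0.4 ms steps to 2000 ms (resolving modes down to a few
  Hz). The residual interpolant bias at 1 kHz is about $-0.5$%.

The plateau $\mathrm{msd}_\infty$ is the mean over the last decile of
times, with a warning when its relative slope exceeds 1% (plateau not
reached). A second, independent route — central-difference velocity
autocorrelation, with the $t \to 0$ singular part captured by the one-sided
difference, with the singular short-time part eliminated through the sum
rule $D(0) = 0$ (exact for bounded substrates), then transformed — agrees
with the primary route to well within 1% and is kept as a cross-check, as
is a mode-decomposition oracle that is closed-form for Gaussian motion
along a periodic trajectory.

## Monte Carlo validation

Two Rcpp random walkers validate the Gaussian sampling chain. The
*thin-fiber walker* takes Gaussian steps in arc length (default
$dt$ = 10 us) and remaps positions through the discretized trajectory;
it reproduces the Gaussian-sampling MSD within sampling error (the
comparison uses z-scores at 20 log-spaced probe times, since the MC errors
are strongly correlated across times and a pointwise criterion over
hundreds of correlated samples would reject exact agreement occasionally).
The *strip walker* implements the undulating cylinder as the 2D region
$|y - a\sin(2\pi x/\lambda)| \le d/2$ with fixed step length $dx$ and a
stay-on-rejection boundary rule; $dt = dx^2/(4 D_0)$ so each Cartesian
component diffuses at $D_0$. Note that the transverse restriction of the
strip is planar, so its straight-geometry reference is the `dim = 1`
analytic spectrum at matched width, not the `dim = 2` cylinder spectrum.
Signals are validated separately by accumulating per-particle dephasing
phases $\Phi_k = \gamma \int g(t)\, y_k(t)\, dt$; the first-cumulant
signal $S = \exp(-\int D(f)|q(f)|^2 df)$ agrees with the phase-accrual
signal to well under 1% at the protocol's b-values (attenuations up to
about 20%) and stays within ~2% up to attenuations of about 60%.

## Encoding and diameter fitting

Waveforms are rectangular PGSE pulses (the four-waveform protocol with
$(G, \delta, \Delta)$ = (58, 12, 80), (46, 15, 77), (57, 5, 87),
(60, 13, 20) in mT/m and ms); b-values are always computed from these
timings via $b = \gamma^2 G^2 \delta^2 (\Delta - \delta/3)$. The encoding
power $|q(f)|^2$ comes from a zero-padded FFT of $q(t)$, stored one-sided
with the density doubled so that $\int_0^\infty |q(f)|^2 df = b$ exactly
(discrete Parseval); the encoding width $e_\Delta$ is the HWHM of the main
lobe of the *two-sided* shape. Three of the protocol's waveforms have
$e_\Delta \approx 6$ Hz and one $\approx 19$ Hz, so nothing above ~50 Hz is
encoded.

The diameter fit is the constrained intra-axonal radial cylinder model:
noise-free signals are matched in least squares against signals generated
from the analytic cylinder spectrum with $D_0$ fixed at 1.7 um$^2$/ms
(not estimated), via a 200-point log-spaced grid search on
$d \in [0.1, 20]$ um plus bounded local refinement. Estimates at a search
bound are flagged rather than silently returned.

## Feature estimation conventions

* $D_{hi}$: mean of $D(f)$ over 900–1000 Hz.
* $f_\Delta$: lowest frequency where $D(f)$ crosses $D_{hi}/2$, linearly
  interpolated; for non-monotone (stochastic) spectra the first upward
  crossing is used.
* $p_{fit}$: straight-line least squares of $\log D$ on $\log f$ over
  $(0, \min(f_\Delta, 20\,\mathrm{Hz})]$, the lowest fitted frequency being
  the grid resolution (0.5 Hz). The upper bound "half of the spectral
  height" only makes sense as the frequency where the spectrum reaches it,
  i.e. $f_\Delta$. On the 15-substrate grid this estimator gives exponents
  in [1.68, 1.99] with median 1.77; the exponent is genuinely sensitive to
  the fit region and grid, which is part of the scientific point — $p$ is
  not a robust invariant of these substrates.
* $k_h$, $k_s$: slopes of through-origin least squares of estimated widths
  on the $k = 1$ predictors (the theory has no intercept). The grid
  calibration gives $k_h \approx 0.34$; the small-amplitude single-mode
  limit is $1/\pi \approx 0.318$, a useful analytic anchor.

## Problem sizes and what the tests show

The package's standard experiment sizes were chosen for a desk-scale
machine: the grid run uses the default time grid above (about 5700 time
samples per substrate), Monte Carlo validations use $10^4$–$10^5$ walkers,
and the strip simulations use step lengths of 0.2–0.4 um. These sizes make
the full analysis chain reproducible in minutes while keeping Monte Carlo
standard errors at the percent level; they are scaled-down study conditions,
and the Monte Carlo comparisons are correspondingly formulated as
statistical (z-score or band-averaged) checks rather than pointwise exact
ones.

The synthetic substrates emulate the geometry of undulating axons — mild,
quasi-sinusoidal planar undulation with amplitudes 1–3 um and wavelengths
10–50 um — and nothing else. Real axons add varying calibre, beading,
three-dimensional tortuosity, membranes with finite permeability, an
extra-axonal compartment, and macroscopic orientation dispersion across
axons; none of these are modelled, so passing tests validate the
undulation-to-spectrum-to-diameter-bias chain, not a complete forward model
of white matter. Within its scope the model is only trusted for mild
undulations ($a/\lambda \lesssim 0.3$; the constructor warns beyond) and
for thin axons: by the strip simulations, undulating cylinders with
$d \lesssim 2$–3 um are signal-indistinguishable from thin fibers under
the protocol, while at $d = 10$ um the cylinder's own restriction
dominates.

## Known limitations

* The thin-fiber spectrum never reaches $D_0$ at high frequency (its
  plateau is $\mu OD \cdot D_0$), which is an artifact of the
  infinitesimally thin idealization; comparisons with cylinders are only
  meaningful below ~50 Hz, where clinical PGSE protocols encode.
* The stochastic-phase generator's parameters are model choices, not
  histology fits; conclusions drawn from the stochastic case depend on
  them.
* Trajectories are two-dimensional; three-dimensional undulation would
  distribute the transverse displacement over two axes.
* The first-cumulant signal model degrades beyond ~60% attenuation; the
  diameter fits stay in the validated low-attenuation regime by
  construction of the protocol.
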