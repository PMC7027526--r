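Package: undufiber
Title: Time-Dependent Diffusion in Undulating Thin Fibers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Toy model of axons as undulating thin fibers for studying
    time-dependent diffusion in the frequency domain. Generates harmonic,
    gamma-ensemble and stochastic-phase fiber substrates, computes transverse
    diffusion spectra D(f) by Gaussian sampling along the fiber arc and by
    Monte Carlo random walks, provides closed-form restricted-diffusion
    spectra (Lorentzian sums over Bessel roots) for planes, cylinders and
    spheres, estimates and predicts spectral features (height, width,
    power-law exponent), synthesizes pulsed-gradient spin-echo signals from
    encoding power spectra, and quantifies the bias incurred when straight
    cylinder models are used to estimate axon diameters from undulating
    fibers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
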