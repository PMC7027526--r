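# Expensive shared fixtures computed once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache))
    assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# full-grid Gaussian-sampling run at the default study conditions
grid_run_cached <- function() cached("grid_run", run_spectra_grid())

protocol_enc_cached <- function()
  cached("protocol_enc", lapply(protocol_waveforms(), encoding_spectrum))
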