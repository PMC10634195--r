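# Shared fixture builders for the test suite. Everything is generated in
# code; no stored data.

fingerprint_axis <- function(by = 4) default_axis(600, 1800, by)

# A single cycle with a hand-injected step-and-hold event: Rayleigh jumps
# by `step` at `start` and every Raman row in the event gains `spectrum`.
make_step_cycle <- function(n = 256, start = 100, step = 10,
                            spectrum = NULL, axis = fingerprint_axis(),
                            noise_sd = 0, baseline = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(spectrum)) spectrum <- rep(0, length(axis))
  rayleigh <- rep(baseline, n)
  raman <- matrix(2, n, length(axis))
  if (noise_sd > 0) {
    rayleigh <- rayleigh + rnorm(n, 0, noise_sd)
    raman <- raman + rnorm(n * length(axis), 0, noise_sd)
  }
  idx <- start:n
  rayleigh[idx] <- rayleigh[idx] + step
  raman[idx, ] <- raman[idx, ] + rep(spectrum, each = length(idx))
  trace_cycle(seq_len(n) * 0.038, rayleigh, raman, axis)
}

# A small labelled spectrum set drawn from the built-in particle classes.
make_class_spectra <- function(classes = c("EV", "LDL"), n_per = 30,
                               axis = fingerprint_axis(), noise_sd = 0.05,
                               jitter = 0.1, seed = 1) {
  set.seed(seed)
  lib <- component_library(axis)
  specs <- default_particle_classes()
  rows <- lapply(classes, function(nm) {
    t(sapply(seq_len(n_per), function(i) {
      20 * make_particle_spectrum(specs[[nm]]$composition, lib,
                                  jitter_sdlog = jitter) +
        rnorm(length(axis), 0, noise_sd)
    }))
  })
  spectrum_set(do.call(rbind, rows), axis, rep(classes, each = n_per))
}
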