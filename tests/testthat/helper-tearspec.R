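# shared helpers for building small deterministic fixtures in code

# a single spectrum on the canonical grid from an intensity vector
spec_from <- function(y, grid = canonical_grid(), class_label = "UNKNOWN") {
  as_spectra(data.frame(wavenumber = grid, intensity = y, class_label = class_label))
}

# fully deterministic generator config: every stochastic component off
noiseless_config <- function(n_subjects = c(Ctr = 1), ...) {
  default_profiles(
    n_subjects = n_subjects, n_replicates = 2,
    noise_sd = 0, subject_sd = c(Ctr = 0, MCI = 0, AD = 0),
    center_jitter_sd = 0, fwhm_jitter_sd = 0,
    gain_sd = 0, tilt_sd = 0, hump_sd = 0, n_humps = 0,
    baseline_scale_sd = 0, ...
  )
}

# small cohort for fast pipeline tests
small_config <- function(...) {
  default_profiles(n_subjects = c(Ctr = 3, MCI = 3, AD = 4), ...)
}
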