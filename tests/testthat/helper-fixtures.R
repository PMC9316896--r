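# Shared fixtures: small instruments and fabricated calibration sets.

# Narrow-range instrument covering only the default calibration window;
# keeps simulation-heavy tests fast without changing the physics.
narrow_instrument <- function(noise = 0.01, baseline = 0.01, scans = 16) {
  instrument_profile(
    wavenumber_min = 1100, wavenumber_max = 1400, grid_step = 2,
    noise_sd_per_scan = noise, baseline_shift_sd = baseline,
    scans_per_spectrum = scans
  )
}

noise_free_instrument <- function(...) {
  narrow_instrument(noise = 0, baseline = 0, ...)
}

default_window <- function() spectral_windows(c(1200.20, 1259.84))

default_prep <- function() preprocess_spec(default_window())

# Wrap a raw predictor matrix as a calibration_set so algebraic PLS
# properties can be tested without the spectral preprocessing chain.
as_calibration_set <- function(X, y) {
  structure(
    list(
      X = X, y = as.numeric(y),
      wavenumber = seq_len(ncol(X)),
      window = rep(1L, ncol(X)),
      prep = preprocess_spec(spectral_windows(c(1, ncol(X))),
                             baseline = "none", centering = "mean")
    ),
    class = "calibration_set"
  )
}

# Construct a replicate vector with an exact sample standard deviation.
replicates_with_sd <- function(target_sd, center = 0.3, n = 10) {
  half <- n / 2
  a <- target_sd * sqrt((n - 1) / n)
  center + c(rep(-a, half), rep(a, half))
}
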