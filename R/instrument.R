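#' Hand-held FTIR instrument profile
#'
#' Describes the measurement geometry and noise behaviour of a hand-held
#' mid-IR spectrometer operated in specular reflectance: the spectral range
#' and sampling interval, the spot area interrogated per measurement, the
#' number of interferometer scans co-averaged into one reported spectrum,
#' and two noise terms -- white per-scan detector noise and a per-measurement
#' baseline shift/tilt modelling coupon-to-coupon surface-roughness
#' variation.
#'
#' Averaging \code{scans_per_spectrum} scans reduces the effective white
#' noise standard deviation to \code{noise_sd_per_scan / sqrt(scans)}; the
#' baseline realization is drawn once per measurement and is not reduced by
#' scan averaging.
#'
#' @param wavenumber_min,wavenumber_max Spectral range, cm^-1.
#' @param grid_step Sampling interval of the wavenumber grid, cm^-1.
#' @param spot_area Area interrogated per spot measurement, mm^2.
#' @param scans_per_spectrum Number of scans averaged into one spectrum.
#' @param noise_sd_per_scan Standard deviation of white noise in a single
#'   scan, absorbance units.
#' @param baseline_shift_sd Standard deviation of the per-measurement
#'   baseline offset and tilt, absorbance units.
#' @return An object of class \code{instrument_profile}.
#' @examples
#' instrument_profile()
#' @export
instrument_profile <- function(wavenumber_min = 650,
                               wavenumber_max = 4000,
                               grid_step = 2,
                               spot_area = 1.76,
                               scans_per_spectrum = 16,
                               noise_sd_per_scan = 0.01,
                               baseline_shift_sd = 0.01) {
  if (wavenumber_min >= wavenumber_max) {
    stop_ftir("ftir_invalid_profile", "wavenumber_min must be < wavenumber_max")
  }
  if (spot_area <= 0) stop_ftir("ftir_invalid_profile", "spot_area must be positive")
  if (grid_step <= 0) stop_ftir("ftir_invalid_profile", "grid_step must be positive")
  if (scans_per_spectrum < 1) {
    stop_ftir("ftir_invalid_profile", "scans_per_spectrum must be >= 1")
  }
  if (noise_sd_per_scan < 0 || baseline_shift_sd < 0) {
    stop_ftir("ftir_invalid_profile", "noise parameters must be non-negative")
  }
  structure(
    list(
      wavenumber_min = wavenumber_min,
      wavenumber_max = wavenumber_max,
      grid_step = grid_step,
      spot_area = spot_area,
      scans_per_spectrum = as.integer(scans_per_spectrum),
      noise_sd_per_scan = noise_sd_per_scan,
      baseline_shift_sd = baseline_shift_sd
    ),
    class = "instrument_profile"
  )
}

#' Wavenumber grid of an instrument profile
#'
#' @param profile An \code{instrument_profile}.
#' @return Ascending numeric vector of wavenumbers, cm^-1.
#' @export
wavenumber_grid <- function(profile) {
  seq(profile$wavenumber_min, profile$wavenumber_max, by = profile$grid_step)
}

#' @export
print.instrument_profile <- function(x, ...) {
  cat(sprintf(
    "<instrument_profile> %g-%g cm^-1 (step %g), spot %g mm^2, %d scans, noise %g AU/scan, baseline sd %g AU\n",
    x$wavenumber_min, x$wavenumber_max, x$grid_step, x$spot_area,
    x$scans_per_spectrum, x$noise_sd_per_scan, x$baseline_shift_sd
  ))
  invisible(x)
}

#' Spectral signature of an active pharmaceutical ingredient
#'
#' A synthetic stand-in for a real API absorbance spectrum: a sum of
#' Gaussian bands, each with a centre (cm^-1), a width (Gaussian sigma,
#' cm^-1) and an amplitude per unit surface density (absorbance units per
#' ug/cm^2). Absorbance scales linearly with surface density, the
#' assumption underlying the calibration model.
#'
#' @param peak_centers Band centres, cm^-1.
#' @param peak_widths Gaussian sigma per band, cm^-1.
#' @param peak_amplitudes Peak absorbance per unit density, AU/(ug/cm^2).
#' @return An object of class \code{api_signature}.
#' @examples
#' default_api_signature()
#' @export
api_signature <- function(peak_centers, peak_widths, peak_amplitudes) {
  n <- length(peak_centers)
  if (length(peak_widths) != n || length(peak_amplitudes) != n || n < 1) {
    stop_ftir("ftir_invalid_signature", "peak vectors must have equal positive length")
  }
  if (any(peak_widths <= 0)) stop_ftir("ftir_invalid_signature", "peak widths must be positive")
  if (any(peak_amplitudes < 0)) stop_ftir("ftir_invalid_signature", "peak amplitudes must be >= 0")
  structure(
    list(
      peak_centers = as.numeric(peak_centers),
      peak_widths = as.numeric(peak_widths),
      peak_amplitudes = as.numeric(peak_amplitudes)
    ),
    class = "api_signature"
  )
}

#' @describeIn api_signature A default signature with a strong band inside
#'   the 1200.20--1259.84 cm^-1 calibration window and a weaker C-H stretch
#'   band near 2940 cm^-1.
#' @export
default_api_signature <- function() {
  api_signature(
    peak_centers = c(1230, 2940),
    peak_widths = c(12, 25),
    peak_amplitudes = c(0.05, 0.02)
  )
}

# Noise-free absorbance of `signature` at unit surface density on `wn`.
signature_response <- function(signature, wn) {
  y <- numeric(length(wn))
  for (i in seq_along(signature$peak_centers)) {
    y <- y + signature$peak_amplitudes[i] *
      exp(-(wn - signature$peak_centers[i])^2 / (2 * signature$peak_widths[i]^2))
  }
  y
}
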