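#' Construct an FTIR spectrum object
#'
#' @param wavenumber Strictly increasing wavenumbers, cm^-1.
#' @param absorbance Absorbance values, same length.
#' @param true_density Simulator ground truth, ug/cm^2 (NA for real data).
#' @param n_scans Number of scans averaged into this spectrum.
#' @return An object of class \code{ftir_spectrum}.
#' @export
ftir_spectrum <- function(wavenumber, absorbance, true_density = NA_real_,
                          n_scans = NA_integer_) {
  if (length(wavenumber) != length(absorbance)) {
    stop_ftir("ftir_invalid_spectrum", "wavenumber and absorbance lengths differ")
  }
  if (length(wavenumber) > 1 && any(diff(wavenumber) <= 0)) {
    stop_ftir("ftir_invalid_spectrum", "wavenumbers must be strictly increasing")
  }
  structure(
    list(
      wavenumber = as.numeric(wavenumber),
      absorbance = as.numeric(absorbance),
      true_density = true_density,
      n_scans = n_scans
    ),
    class = "ftir_spectrum"
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ftir_spectrum> %d channels, %g-%g cm^-1%s\n",
    length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
    if (is.na(x$true_density)) "" else sprintf(", true density %.4g ug/cm^2", x$true_density)
  ))
  invisible(x)
}

# One baseline realization: random offset plus random tilt across the range,
# both with sd = baseline_shift_sd. Models coupon-to-coupon surface
# roughness; drawn once per measurement, unaffected by scan averaging.
draw_baseline <- function(wn, instrument) {
  b0 <- stats::rnorm(1, 0, instrument$baseline_shift_sd)
  b1 <- stats::rnorm(1, 0, instrument$baseline_shift_sd)
  span <- max(wn) - min(wn)
  t <- if (span > 0) (wn - mean(range(wn))) / span else rep(0, length(wn))
  b0 + b1 * t
}

simulate_one <- function(density, signature, instrument, wn,
                         baseline = NULL) {
  clean <- density * signature_response(signature, wn)
  if (is.null(baseline)) baseline <- draw_baseline(wn, instrument)
  noise_sd <- instrument$noise_sd_per_scan / sqrt(instrument$scans_per_spectrum)
  noise <- if (noise_sd > 0) stats::rnorm(length(wn), 0, noise_sd) else 0
  ftir_spectrum(wn, clean + baseline + noise,
                true_density = density,
                n_scans = instrument$scans_per_spectrum)
}

#' Simulate one scan-averaged FTIR measurement
#'
#' Produces the spectrum a hand-held FTIR would report for a spot of known
#' local surface density: the API's Gaussian-band response scaled linearly
#' by density, plus one random baseline offset/tilt per measurement
#' (surface-roughness model) and white noise whose standard deviation is
#' reduced by scan averaging to \code{noise_sd_per_scan / sqrt(scans)}.
#'
#' @param density Local surface density at the measured spot, ug/cm^2.
#' @param signature An \code{\link{api_signature}}.
#' @param instrument An \code{\link{instrument_profile}}.
#' @param seed Integer seed or \code{NULL}.
#' @return An \code{\link{ftir_spectrum}} carrying the true density.
#' @examples
#' sp <- simulate_measurement(0.6, default_api_signature(),
#'                            instrument_profile(), seed = 1)
#' @export
simulate_measurement <- function(density, signature, instrument, seed = NULL) {
  if (density < 0) stop_ftir("ftir_invalid_target", "density must be >= 0")
  wn <- wavenumber_grid(instrument)
  with_seed(seed, simulate_one(density, signature, instrument, wn))
}

#' Generate a labelled calibration set of spectra
#'
#' Simulates \code{replicates} spectra at each surface-density level, each
#' with its own baseline and noise realization, and attaches the true
#' labels -- the synthetic analogue of measuring printed calibration
#' coupons.
#'
#' @param levels Surface-density levels, ug/cm^2.
#' @param replicates Spectra per level.
#' @param signature An \code{\link{api_signature}}.
#' @param instrument An \code{\link{instrument_profile}}.
#' @param seed Integer seed or \code{NULL}.
#' @return A list with \code{spectra} (list of \code{ftir_spectrum}) and
#'   \code{density} (numeric labels, ug/cm^2), class
#'   \code{calibration_spectra}.
#' @export
generate_calibration_set <- function(levels, replicates, signature,
                                     instrument, seed = NULL) {
  if (length(levels) == 0) {
    stop_ftir("ftir_invalid_target", "at least one calibration level is required")
  }
  if (any(levels < 0)) stop_ftir("ftir_invalid_target", "levels must be >= 0")
  if (replicates < 1) stop_ftir("ftir_invalid_target", "replicates must be >= 1")
  wn <- wavenumber_grid(instrument)
  density <- rep(as.numeric(levels), each = replicates)
  spectra <- with_seed(seed, lapply(density, function(d) {
    simulate_one(d, signature, instrument, wn)
  }))
  structure(list(spectra = spectra, density = density),
            class = "calibration_spectra")
}

#' Fixed-point pseudo-blank replicate spectra
#'
#' Emulates repeated measurement of a low-concentration coupon from one
#' fixed point without moving the instrument or the sample: all replicates
#' share the same true local density and the same baseline realization
#' (fixed optics, constant detector temperature); only the per-scan white
#' noise differs between replicates. This is the replicate design used to
#' estimate the measurement standard deviation for LOD/LOQ.
#'
#' @param density True local density at the fixed point, ug/cm^2.
#' @param n Number of replicate spectra (>= 2; 10 for a reportable LOQ).
#' @param signature An \code{\link{api_signature}}.
#' @param instrument An \code{\link{instrument_profile}}.
#' @param seed Integer seed or \code{NULL}.
#' @return A \code{calibration_spectra} object with \code{n} spectra at one
#'   shared density.
#' @export
generate_pseudo_blank_replicates <- function(density, n, signature,
                                             instrument, seed = NULL) {
  if (n < 2) stop_ftir("ftir_invalid_target", "at least 2 replicates are required")
  if (density < 0) stop_ftir("ftir_invalid_target", "density must be >= 0")
  wn <- wavenumber_grid(instrument)
  spectra <- with_seed(seed, {
    baseline <- draw_baseline(wn, instrument)
    lapply(seq_len(n), function(i) {
      simulate_one(density, signature, instrument, wn, baseline = baseline)
    })
  })
  structure(list(spectra = spectra, density = rep(density, n)),
            class = "calibration_spectra")
}
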