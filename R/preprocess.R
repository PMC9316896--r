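#' Spectral window set
#'
#' Calibration models are built not on the full mid-IR range but on narrow
#' regions of interest containing the analyte's strong bands (for one API
#' a single window 1200.20--1259.84 cm^-1; for another, two windows
#' 1187.15--1289.65 and 2884.96--2993.05 cm^-1). Window membership uses
#' closed intervals at both endpoints.
#'
#' @param windows A list of numeric length-2 vectors \code{c(low, high)} in
#'   cm^-1, or a single such vector. Windows must not overlap.
#' @return An object of class \code{spectral_windows}.
#' @examples
#' spectral_windows(c(1200.20, 1259.84))
#' spectral_windows(list(c(1187.15, 1289.65), c(2884.96, 2993.05)))
#' @export
spectral_windows <- function(windows) {
  if (is.numeric(windows)) windows <- list(windows)
  if (length(windows) == 0) {
    stop_ftir("ftir_invalid_windows", "at least one window is required")
  }
  for (w in windows) {
    if (length(w) != 2 || !is.numeric(w) || w[1] >= w[2]) {
      stop_ftir("ftir_invalid_windows", "each window must be c(low, high) with low < high")
    }
  }
  o <- order(vapply(windows, `[`, numeric(1), 1))
  windows <- windows[o]
  if (length(windows) > 1) {
    for (i in seq_len(length(windows) - 1)) {
      if (windows[[i]][2] >= windows[[i + 1]][1]) {
        stop_ftir("ftir_invalid_windows", "windows must not overlap")
      }
    }
  }
  structure(list(windows = windows), class = "spectral_windows")
}

#' Restrict a spectrum to calibration windows
#'
#' Retains the channels whose wavenumber lies inside any window (closed
#' intervals), window order preserved, ascending within each window.
#'
#' @param spectrum An \code{\link{ftir_spectrum}}.
#' @param windows A \code{\link{spectral_windows}}.
#' @return A list with \code{wavenumber}, \code{absorbance} and
#'   \code{window} (integer window index per retained channel).
#' @export
restrict_to_windows <- function(spectrum, windows) {
  wn <- spectrum$wavenumber
  out_wn <- numeric(0); out_ab <- numeric(0); out_win <- integer(0)
  for (i in seq_along(windows$windows)) {
    w <- windows$windows[[i]]
    if (w[1] < min(wn) || w[2] > max(wn)) {
      stop_ftir(
        "ftir_window_coverage",
        sprintf("window %g-%g cm^-1 not covered by spectrum grid (%g-%g)",
                w[1], w[2], min(wn), max(wn))
      )
    }
    idx <- which(wn >= w[1] & wn <= w[2])
    out_wn <- c(out_wn, wn[idx])
    out_ab <- c(out_ab, spectrum$absorbance[idx])
    out_win <- c(out_win, rep.int(i, length(idx)))
  }
  list(wavenumber = out_wn, absorbance = out_ab, window = out_win)
}

#' Two-point linear baseline correction per window
#'
#' Subtracts from each window the straight line through its first and last
#' channel, removing the per-measurement baseline offset and tilt caused by
#' coupon-to-coupon surface roughness. \code{mode = "none"} is the
#' identity.
#'
#' @param channels A restricted-channel list as returned by
#'   \code{\link{restrict_to_windows}} (fields \code{wavenumber},
#'   \code{absorbance}, \code{window}).
#' @param mode \code{"linear-per-window"} or \code{"none"}.
#' @return The same list with corrected \code{absorbance}.
#' @export
baseline_correct <- function(channels, mode = c("linear-per-window", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(channels)
  ab <- channels$absorbance
  for (i in unique(channels$window)) {
    idx <- which(channels$window == i)
    if (length(idx) < 3) {
      stop_ftir(
        "ftir_degenerate_window",
        sprintf("window %d has %d channel(s); linear baseline correction needs >= 3",
                i, length(idx))
      )
    }
    x <- channels$wavenumber[idx]
    y <- ab[idx]
    k <- length(idx)
    slope <- (y[k] - y[1]) / (x[k] - x[1])
    ab[idx] <- y - (y[1] + slope * (x - x[1]))
  }
  channels$absorbance <- ab
  channels
}

#' Preprocessing specification
#'
#' Bundles the window set, baseline mode and centering mode applied before
#' the calibration fit; recorded in the fitted model so prediction applies
#' identical preprocessing.
#'
#' @param windows A \code{\link{spectral_windows}} (or input accepted by it).
#' @param baseline \code{"linear-per-window"} or \code{"none"}.
#' @param centering \code{"mean"} or \code{"none"}.
#' @return An object of class \code{preprocess_spec}.
#' @export
preprocess_spec <- function(windows,
                            baseline = c("linear-per-window", "none"),
                            centering = c("mean", "none")) {
  if (!inherits(windows, "spectral_windows")) windows <- spectral_windows(windows)
  structure(
    list(windows = windows,
         baseline = match.arg(baseline),
         centering = match.arg(centering)),
    class = "preprocess_spec"
  )
}

# Apply windows + baseline to one spectrum; returns the channel vector.
preprocess_channels <- function(spectrum, prep) {
  ch <- restrict_to_windows(spectrum, prep$windows)
  ch <- baseline_correct(ch, prep$baseline)
  ch
}

#' Assemble a calibration matrix from labelled spectra
#'
#' Applies the preprocessing (window restriction and baseline correction)
#' to every spectrum of a labelled set and stacks the retained channels
#' into the predictor matrix used by \code{\link{fit_pls}}.
#'
#' @param cal_spectra A \code{calibration_spectra} object (see
#'   \code{\link{generate_calibration_set}}), or a list of spectra.
#' @param prep A \code{\link{preprocess_spec}}.
#' @param density Responses in ug/cm^2; taken from \code{cal_spectra} when
#'   omitted.
#' @return An object of class \code{calibration_set}: predictor matrix
#'   \code{X} (rows = spectra), response \code{y}, channel wavenumbers and
#'   window ids, and the preprocessing record.
#' @export
build_calibration_set <- function(cal_spectra, prep, density = NULL) {
  spectra <- if (inherits(cal_spectra, "calibration_spectra")) {
    cal_spectra$spectra
  } else {
    cal_spectra
  }
  y <- density %||% cal_spectra$density
  if (length(spectra) != length(y) || length(y) < 2) {
    stop_ftir("ftir_degenerate_data", "need >= 2 spectra with matching responses")
  }
  first <- preprocess_channels(spectra[[1]], prep)
  X <- matrix(NA_real_, nrow = length(spectra), ncol = length(first$absorbance))
  X[1, ] <- first$absorbance
  for (i in seq_along(spectra)[-1]) {
    ch <- preprocess_channels(spectra[[i]], prep)
    if (length(ch$absorbance) != ncol(X)) {
      stop_ftir("ftir_window_coverage", "spectra have inconsistent channel grids")
    }
    X[i, ] <- ch$absorbance
  }
  structure(
    list(X = X, y = as.numeric(y),
         wavenumber = first$wavenumber, window = first$window,
         prep = prep),
    class = "calibration_set"
  )
}
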