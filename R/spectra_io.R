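# Spectrum interchange: plain two-column text (bit-exact round trip) and a
# JCAMP-DX subset (XYDATA, AFFN fixed point) for instrument interchange.

#' Write a spectrum to disk
#'
#' Two dialects are supported. \code{"two-column-text"} writes
#' \code{#}-prefixed header lines followed by wavenumber/absorbance pairs
#' at full double precision (\code{\%.17g}); reading it back reproduces the
#' values bit-exactly. \code{"jcamp-dx"} writes a minimal JCAMP-DX record
#' (\code{##XYDATA=(X++(Y..Y))}, AFFN fixed point, YFACTOR 1e-8) for
#' equally spaced data, adequate for interchange at 1e-8 absorbance
#' resolution.
#'
#' @param spectrum An \code{\link{ftir_spectrum}}.
#' @param path Output file path.
#' @param dialect \code{"two-column-text"} or \code{"jcamp-dx"}.
#' @return \code{path}, invisibly.
#' @export
write_spectrum <- function(spectrum, path,
                           dialect = c("two-column-text", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (dialect == "two-column-text") {
    lines <- c(
      "# ftirclean spectrum",
      "# columns: wavenumber_cm-1 absorbance",
      sprintf("%.17g %.17g", spectrum$wavenumber, spectrum$absorbance)
    )
  } else {
    n <- length(spectrum$wavenumber)
    steps <- diff(spectrum$wavenumber)
    if (n > 2 && diff(range(steps)) > 1e-6 * mean(steps)) {
      stop_ftir("ftir_parse_error",
                "jcamp-dx dialect requires an equally spaced wavenumber grid")
    }
    yfac <- 1e-8
    yi <- round(spectrum$absorbance / yfac)
    lines <- c(
      "##TITLE=ftirclean spectrum",
      "##JCAMP-DX=4.24",
      "##DATA TYPE=INFRARED SPECTRUM",
      "##XUNITS=1/CM",
      "##YUNITS=ABSORBANCE",
      "##XFACTOR=1",
      sprintf("##YFACTOR=%.10g", yfac),
      sprintf("##FIRSTX=%.10f", spectrum$wavenumber[1]),
      sprintf("##LASTX=%.10f", spectrum$wavenumber[n]),
      sprintf("##NPOINTS=%d", n),
      "##XYDATA=(X++(Y..Y))",
      vapply(seq(1, n, by = 6), function(i) {
        j <- min(i + 5, n)
        paste(c(sprintf("%.4f", spectrum$wavenumber[i]),
                sprintf("%.0f", yi[i:j])), collapse = " ")
      }, character(1)),
      "##END="
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a spectrum from disk
#'
#' Parses either interchange dialect written by \code{\link{write_spectrum}}.
#' Wavenumbers in descending order are re-sorted ascending with a warning;
#' malformed or truncated files raise a parse error naming the offending
#' line.
#'
#' @param path Input file path.
#' @param dialect \code{"two-column-text"} or \code{"jcamp-dx"}.
#' @return An \code{\link{ftir_spectrum}} (with unknown true density).
#' @export
read_spectrum <- function(path, dialect = c("two-column-text", "jcamp-dx")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_ftir("ftir_parse_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (dialect == "two-column-text") {
    wn <- numeric(0); ab <- numeric(0)
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "#")) next
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:],;]+")[[1]]))
      if (length(vals) != 2 || anyNA(vals)) {
        stop_ftir("ftir_parse_error",
                  sprintf("%s: cannot parse line %d: '%s'", path, i, lines[i]))
      }
      wn <- c(wn, vals[1]); ab <- c(ab, vals[2])
    }
    if (length(wn) == 0) {
      stop_ftir("ftir_parse_error", sprintf("%s: no data lines", path))
    }
  } else {
    yfac <- 1
    firstx <- NA_real_; lastx <- NA_real_; npoints <- NA_integer_
    in_data <- FALSE
    ab <- numeric(0)
    for (i in seq_along(lines)) {
      ln <- trimws(lines[i])
      if (ln == "") next
      if (startsWith(ln, "##")) {
        if (grepl("^##YFACTOR=", ln)) yfac <- as.numeric(sub("^##YFACTOR=", "", ln))
        if (grepl("^##FIRSTX=", ln)) firstx <- as.numeric(sub("^##FIRSTX=", "", ln))
        if (grepl("^##LASTX=", ln)) lastx <- as.numeric(sub("^##LASTX=", "", ln))
        if (grepl("^##NPOINTS=", ln)) npoints <- as.integer(sub("^##NPOINTS=", "", ln))
        if (grepl("^##XYDATA=", ln)) in_data <- TRUE
        if (grepl("^##END", ln)) in_data <- FALSE
        next
      }
      if (!in_data) next
      vals <- suppressWarnings(as.numeric(strsplit(ln, "[[:space:]]+")[[1]]))
      if (length(vals) < 2 || anyNA(vals)) {
        stop_ftir("ftir_parse_error",
                  sprintf("%s: cannot parse XYDATA line %d: '%s'", path, i, lines[i]))
      }
      ab <- c(ab, vals[-1] * yfac)
    }
    if (length(ab) == 0) {
      stop_ftir("ftir_parse_error", sprintf("%s: no XYDATA block", path))
    }
    if (anyNA(c(firstx, lastx, npoints))) {
      stop_ftir("ftir_parse_error",
                sprintf("%s: missing FIRSTX/LASTX/NPOINTS headers", path))
    }
    if (length(ab) != npoints) {
      stop_ftir("ftir_parse_error",
                sprintf("%s: NPOINTS=%d but %d values read (truncated file?)",
                        path, npoints, length(ab)))
    }
    wn <- seq(firstx, lastx, length.out = npoints)
  }
  if (length(wn) > 1 && all(diff(wn) < 0)) {
    warning("wavenumbers were descending; re-sorted ascending")
    o <- order(wn)
    wn <- wn[o]; ab <- ab[o]
  } else if (length(wn) > 1 && any(diff(wn) <= 0)) {
    if (anyDuplicated(wn)) {
      stop_ftir("ftir_parse_error", sprintf("%s: duplicate wavenumbers", path))
    }
    warning("wavenumbers were unordered; re-sorted ascending")
    o <- order(wn)
    wn <- wn[o]; ab <- ab[o]
  }
  ftir_spectrum(wn, ab)
}
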