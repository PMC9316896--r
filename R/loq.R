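#' Limits of detection and quantification from replicate measurements
#'
#' Estimates LOD and LOQ from the standard deviation of repeated
#' fixed-point measurements of a low-concentration (pseudo-blank) coupon:
#' \code{lod = lod_k * sd}, \code{loq = loq_k * sd} with the sample (n-1)
#' standard deviation of the model-predicted surface densities. The
#' default multipliers 3.3 and 10 follow the ICH Q2 convention for the
#' standard-deviation approach. A reportable LOQ requires at least 10
#' independent replicates; with 2--9 replicates the result is returned but
#' flagged exploratory.
#'
#' Replicates are predicted concentrations rather than raw absorbances, so
#' the LOQ reflects the whole measurement chain (instrument noise through
#' preprocessing and the calibration model).
#'
#' @param replicates Numeric vector of predicted densities, ug/cm^2, from
#'   fixed-point repeat measurements.
#' @param lod_k,loq_k LOD and LOQ multipliers applied to the replicate SD.
#' @param strict Require >= 10 replicates (error otherwise). With
#'   \code{strict = FALSE}, 2--9 replicates give an exploratory result.
#' @param note Free-text provenance (detector temperature, background
#'   status).
#' @return An object of class \code{loq_result}: \code{sd}, \code{lod},
#'   \code{loq}, \code{n}, \code{lod_k}, \code{loq_k}, \code{exploratory},
#'   \code{degenerate} (TRUE when sd is 0), \code{note}.
#' @examples
#' x <- c(0.25, 0.31, 0.28, 0.35, 0.30, 0.27, 0.33, 0.29, 0.32, 0.30)
#' loq_from_replicates(x)
#' @export
loq_from_replicates <- function(replicates, lod_k = 3.3, loq_k = 10,
                                strict = TRUE, note = "") {
  if (length(replicates) < 2) {
    stop_ftir("ftir_insufficient_sample", "LOQ needs at least 2 replicates")
  }
  if (any(!is.finite(replicates))) {
    stop_ftir("ftir_invalid_params", "replicates must all be finite")
  }
  if (lod_k <= 0 || loq_k <= 0 || loq_k <= lod_k) {
    stop_ftir("ftir_invalid_params", "need 0 < lod_k < loq_k")
  }
  exploratory <- length(replicates) < 10
  if (exploratory && strict) {
    stop_ftir(
      "ftir_insufficient_sample",
      sprintf("a reportable LOQ needs >= 10 replicates (got %d); use strict = FALSE for an exploratory estimate",
              length(replicates))
    )
  }
  s <- stats::sd(replicates)
  structure(
    list(
      sd = s,
      lod = lod_k * s,
      loq = loq_k * s,
      n = length(replicates),
      lod_k = lod_k,
      loq_k = loq_k,
      exploratory = exploratory,
      degenerate = s == 0,
      note = note
    ),
    class = "loq_result"
  )
}

#' @export
print.loq_result <- function(x, ...) {
  cat(sprintf(
    "<loq_result> n = %d replicates, sd = %.4g: LOD = %.4g, LOQ = %.4g ug/cm^2 (k = %.3g/%.3g)%s%s\n",
    x$n, x$sd, x$lod, x$loq, x$lod_k, x$loq_k,
    if (x$exploratory) " [exploratory: n < 10]" else "",
    if (x$degenerate) " [degenerate: zero sd]" else ""
  ))
  invisible(x)
}

#' Enforce the calibration floor on a fitted model
#'
#' Records the LOQ as the model's calibration floor: predictions below it
#' carry the \code{below_floor} flag, and a calibration whose training
#' range starts below the floor is rejected outright -- the calibration
#' model must not be developed below the LOQ, and validation coupons must
#' be prepared above it.
#'
#' @param model A \code{pls_model}.
#' @param loq The quantification limit, ug/cm^2 (a \code{loq_result} is
#'   also accepted). A floor of 0 is a no-op.
#' @return The model with \code{calibration_floor} set.
#' @export
apply_calibration_floor <- function(model, loq) {
  if (inherits(loq, "loq_result")) loq <- loq$loq
  if (!is.finite(loq) || loq < 0) {
    stop_ftir("ftir_invalid_params", "loq must be a finite value >= 0")
  }
  if (loq == 0) return(model)
  if (model$training_range[1] < loq) {
    stop_ftir(
      "ftir_invalid_calibration",
      sprintf("training minimum %.4g ug/cm^2 lies below the LOQ floor %.4g; the calibration must not be developed below the LOQ",
              model$training_range[1], loq)
    )
  }
  model$calibration_floor <- loq
  model
}
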