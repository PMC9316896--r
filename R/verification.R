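#' Verification configuration
#'
#' Settings for the pass/fail verdict at one hard-to-clean location: the
#' visual cleanliness limit that gates all instrumental measurement, the
#' residue acceptance limit (RAL), the required number of measurement
#' points, and the margin-of-error parameters defining the expected
#' interval for the 10-point mean.
#'
#' @param visual_limit Visual cleanliness limit, ug/cm^2.
#' @param ral Residue acceptance limit, ug/cm^2; must be >= the visual
#'   limit (a surface failing visual inspection is recleaned, never
#'   measured).
#' @param required_samples Measurement points per location (>= 2).
#' @param moe A \code{\link{moe_params}}; its RAL defaults to \code{ral}.
#' @return An object of class \code{verification_config}.
#' @export
verification_config <- function(visual_limit = 0.6, ral = 1,
                                required_samples = 10,
                                moe = NULL) {
  if (ral <= 0) stop_ftir("ftir_invalid_params", "ral must be positive")
  if (ral < visual_limit) {
    stop_ftir("ftir_invalid_params",
              "ral below the visual limit is invalid: a visually clean surface could still fail")
  }
  if (required_samples < 2) {
    stop_ftir("ftir_invalid_params", "required_samples must be >= 2")
  }
  moe <- moe %||% moe_params(mean = visual_limit, ral = ral)
  structure(
    list(visual_limit = visual_limit, ral = ral,
         required_samples = as.integer(required_samples), moe = moe),
    class = "verification_config"
  )
}

#' Measurements collected at one location
#'
#' @param predicted Model-predicted surface densities, ug/cm^2.
#' @param visual_pass Did the location pass visual inspection?
#' @param label Location label.
#' @param below_floor Optional logical flags (below-LOQ) per measurement.
#' @return An object of class \code{location_measurements}.
#' @export
location_measurements <- function(predicted, visual_pass = TRUE,
                                  label = "location",
                                  below_floor = NULL) {
  structure(
    list(predicted = as.numeric(predicted),
         visual_pass = isTRUE(visual_pass),
         label = label,
         below_floor = below_floor %||% rep(FALSE, length(predicted))),
    class = "location_measurements"
  )
}

#' Verdict for one hard-to-clean location
#'
#' Applies the verification logic: if visual inspection failed, the
#' verdict is \code{not-evaluated-visual-fail} and no statistics are
#' computed (the surface is recleaned, not measured). Otherwise the mean
#' of the measurements is compared with the expected interval for a mean
#' of \code{required_samples} points and with the RAL; the verdict is
#' \code{pass} when the mean does not exceed the RAL, \code{fail} when it
#' does, and \code{inconclusive} (with a reason) when the measurement
#' count is wrong.
#'
#' @param meas A \code{\link{location_measurements}}.
#' @param cfg A \code{\link{verification_config}}.
#' @return A one-row data.frame: \code{location}, \code{verdict},
#'   \code{mean}, \code{lower}, \code{upper}, \code{within_interval},
#'   \code{ral_compliant}, \code{n_below_floor}, \code{reason}.
#' @examples
#' cfg <- verification_config()
#' verify_location(location_measurements(rep(0.55, 10)), cfg)
#' @export
verify_location <- function(meas, cfg) {
  blank <- data.frame(
    location = meas$label, verdict = NA_character_,
    mean = NA_real_, lower = NA_real_, upper = NA_real_,
    within_interval = NA, ral_compliant = NA,
    n_below_floor = NA_integer_, reason = "",
    stringsAsFactors = FALSE
  )
  if (!meas$visual_pass) {
    blank$verdict <- "not-evaluated-visual-fail"
    blank$reason <- "visual inspection failed; surface must be recleaned"
    return(blank)
  }
  if (length(meas$predicted) != cfg$required_samples) {
    blank$verdict <- "inconclusive"
    blank$reason <- sprintf("expected %d measurements, got %d",
                            cfg$required_samples, length(meas$predicted))
    return(blank)
  }
  iv <- mean_interval(cfg$moe, cfg$required_samples)
  m <- mean(meas$predicted)
  blank$mean <- m
  blank$lower <- iv$lower
  blank$upper <- iv$upper
  blank$within_interval <- m >= iv$lower && m <= iv$upper
  blank$ral_compliant <- m <= cfg$ral
  blank$n_below_floor <- sum(meas$below_floor)
  blank$verdict <- if (m <= cfg$ral) "pass" else "fail"
  blank
}

#' Verdicts for several locations
#'
#' @param measurements A list of \code{\link{location_measurements}}.
#' @param cfg A \code{\link{verification_config}}.
#' @return A data.frame with one row per location (see
#'   \code{\link{verify_location}}).
#' @export
verify_locations <- function(measurements, cfg) {
  if (length(measurements) == 0) {
    return(data.frame(
      location = character(0), verdict = character(0),
      mean = numeric(0), lower = numeric(0), upper = numeric(0),
      within_interval = logical(0), ral_compliant = logical(0),
      n_below_floor = integer(0), reason = character(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, lapply(measurements, verify_location, cfg = cfg))
}

#' Write a verification report
#'
#' Deterministic serialization of a verification table, densities at three
#' decimals. \code{"delimited-table"} writes a tab-separated table;
#' \code{"human-readable-text"} writes an aligned plain-text report.
#' Writing the same report twice produces byte-identical files.
#'
#' @param report A data.frame from \code{\link{verify_locations}}.
#' @param path Output file path.
#' @param format \code{"delimited-table"} or \code{"human-readable-text"}.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("delimited-table", "human-readable-text")) {
  format <- match.arg(format)
  fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))
  cols <- c("location", "verdict", "mean", "lower", "upper",
            "within_interval", "ral_compliant", "reason")
  tab <- data.frame(
    location = as.character(report$location),
    verdict = as.character(report$verdict),
    mean = fmt3(report$mean),
    lower = fmt3(report$lower),
    upper = fmt3(report$upper),
    within_interval = as.character(report$within_interval),
    ral_compliant = as.character(report$ral_compliant),
    reason = as.character(report$reason),
    stringsAsFactors = FALSE
  )
  if (format == "delimited-table") {
    lines <- c(
      paste(cols, collapse = "\t"),
      apply(tab, 1, paste, collapse = "\t")
    )
  } else {
    lines <- c(
      "Cleaning verification report",
      "============================",
      ""
    )
    for (i in seq_len(nrow(tab))) {
      lines <- c(lines,
        sprintf("Location: %s", tab$location[i]),
        sprintf("  Verdict: %s", tab$verdict[i]),
        sprintf("  Mean surface residue: %s ug/cm^2", tab$mean[i]),
        sprintf("  Expected interval: %s - %s ug/cm^2", tab$lower[i], tab$upper[i]),
        sprintf("  Within interval: %s; RAL compliant: %s",
                tab$within_interval[i], tab$ral_compliant[i]),
        if (nzchar(tab$reason[i])) sprintf("  Note: %s", tab$reason[i]) else character(0),
        ""
      )
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Default pipeline configuration
#'
#' The end-to-end demonstration conditions: visual limit 0.6 ug/cm^2,
#' RAL 1, 50\% RSD planning assumption at 99.73\% confidence, calibration
#' levels 0.6--3.0 ug/cm^2 with 5 replicates, a 10-replicate pseudo blank
#' at 0.3 ug/cm^2, and three by-hand coupons at the visual limit measured
#' at 10 random spots each.
#'
#' @return A named list accepted by \code{\link{run_pipeline}}.
#' @export
default_pipeline_config <- function() {
  list(
    visual_limit = 0.6,
    ral = 1,
    sd = 0.3,
    confidence = 0.9973,
    required_samples = 10L,
    n_max = 30L,
    target_cpk = 1.67,
    calibration_levels = c(0.6, 1.2, 1.8, 2.4, 3.0),
    calibration_replicates = 5L,
    max_components = 4L,
    cv_folds = 5L,
    window_low = 1200.20,
    window_high = 1259.84,
    pseudo_blank_density = 0.3,
    pseudo_blank_replicates = 10L,
    n_coupons = 3L,
    coupon_mode = "by-hand"
  )
}

#' Run the full cleaning-verification pipeline
#'
#' Executes the whole workflow on synthetic data: simulate a calibration
#' set and fit the PLS model (component count by cross-validation),
#' estimate LOD/LOQ from fixed-point pseudo-blank replicates and apply the
#' calibration floor, compute the capability curve and the sample-size
#' recommendation, then simulate coupons at the visual limit, measure each
#' at the required number of random spots, predict, and issue verdicts.
#' Reruns with the same seed are bit-identical.
#'
#' @param config A named list (see \code{\link{default_pipeline_config}})
#'   or the path of a flat YAML file with the same keys.
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Optional directory; when given, the capability curve
#'   (TSV), the serialized model (JSON), the LOQ summary (TSV) and the
#'   verification report (TSV and text) are written there.
#' @return A list: \code{config}, \code{seed}, \code{model},
#'   \code{components_cv}, \code{loq}, \code{capability},
#'   \code{sample_size}, \code{verification}, \code{measurements}.
#' @export
run_pipeline <- function(config = default_pipeline_config(), seed = 1,
                         out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_pipeline_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown) > 0) {
    stop_ftir("ftir_invalid_params",
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(base, config)
  if (cfg$ral < cfg$visual_limit) {
    stop_ftir("ftir_invalid_params", "config rejected: ral below visual_limit")
  }
  instrument <- instrument_profile()
  signature <- default_api_signature()
  prep <- preprocess_spec(spectral_windows(c(cfg$window_low, cfg$window_high)))

  # --- calibrate ---
  cal_spectra <- generate_calibration_set(
    cfg$calibration_levels, cfg$calibration_replicates,
    signature, instrument, seed = child_seed(seed, 1L)
  )
  cal <- build_calibration_set(cal_spectra, prep)
  cv <- choose_components_cv(cal, cfg$max_components, folds = cfg$cv_folds,
                             seed = child_seed(seed, 2L))
  model <- fit_pls(cal, cv$n_components)

  # --- loq ---
  blanks <- generate_pseudo_blank_replicates(
    cfg$pseudo_blank_density, cfg$pseudo_blank_replicates,
    signature, instrument, seed = child_seed(seed, 3L)
  )
  blank_pred <- predict(model, blanks$spectra)$density
  loq <- loq_from_replicates(blank_pred,
                             note = "fixed point; shared baseline; simulated")
  model <- apply_calibration_floor(model, loq)

  # --- sample size ---
  params <- moe_params(mean = cfg$visual_limit, sd = cfg$sd,
                       confidence = cfg$confidence, ral = cfg$ral)
  curve <- capability_curve(params, cfg$n_max)
  sample_size <- min_samples_for_cpk(cfg$target_cpk, params)

  # --- verify ---
  vcfg <- verification_config(cfg$visual_limit, cfg$ral,
                              cfg$required_samples, moe = params)
  dep <- deposition_profile(mode = cfg$coupon_mode)
  measurements <- lapply(seq_len(cfg$n_coupons), function(i) {
    s_cp <- child_seed(seed, 10L + 3L * i)
    coupon <- generate_coupon(cfg$visual_limit, dep, seed = s_cp)
    dens <- sample_spots_random(coupon, cfg$required_samples,
                                instrument$spot_area,
                                seed = child_seed(seed, 11L + 3L * i))
    spectra <- with_seed(child_seed(seed, 12L + 3L * i), {
      wn <- wavenumber_grid(instrument)
      lapply(dens, function(d) simulate_one(d, signature, instrument, wn))
    })
    pred <- predict(model, spectra)
    location_measurements(pred$density,
                          visual_pass = TRUE,
                          label = sprintf("coupon-%d", i),
                          below_floor = pred$below_floor)
  })
  report <- verify_locations(measurements, vcfg)

  bundle <- list(
    config = cfg, seed = seed,
    model = model, components_cv = cv, loq = loq,
    capability = curve, sample_size = sample_size,
    verification = report, measurements = measurements
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      within(curve, {
        moe <- round(moe, 6); lower <- round(lower, 6)
        upper <- round(upper, 6); cpk <- round(cpk, 6)
      }),
      file.path(out_dir, "capability_curve.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    write_pls_model(model, file.path(out_dir, "pls_model.json"))
    writeLines(
      c("statistic\tvalue",
        sprintf("n\t%d", loq$n),
        sprintf("sd\t%.6f", loq$sd),
        sprintf("lod\t%.6f", loq$lod),
        sprintf("loq\t%.6f", loq$loq)),
      file.path(out_dir, "loq.tsv")
    )
    write_report(report, file.path(out_dir, "verification_report.tsv"),
                 "delimited-table")
    write_report(report, file.path(out_dir, "verification_report.txt"),
                 "human-readable-text")
  }
  bundle
}
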