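# Spectrum simulation: linearity, scan averaging, replicate structure, I/O.

test_that("zero density with zero noise gives a flat zero spectrum", {
  sp <- simulate_measurement(0, default_api_signature(),
                             noise_free_instrument(), seed = 1)
  expect_true(all(sp$absorbance == 0))
  expect_identical(sp$n_scans, 16L)
})

test_that("noise-free absorbance is exactly proportional to density", {
  inst <- noise_free_instrument()
  sig <- default_api_signature()
  s1 <- simulate_measurement(0.7, sig, inst, seed = 1)
  s2 <- simulate_measurement(1.4, sig, inst, seed = 2)
  expect_equal(s2$absorbance, 2 * s1$absorbance, tolerance = 1e-12)
})

test_that("scan averaging reduces channel noise by sqrt(n_scans)", {
  sig <- api_signature(1250, 10, 0.05)
  inst <- instrument_profile(
    wavenumber_min = 1300, wavenumber_max = 1340, grid_step = 2,
    noise_sd_per_scan = 0.02, baseline_shift_sd = 0, scans_per_spectrum = 16
  )
  # flat region far from the band: channel value is pure averaged noise
  set.seed(61)
  vals <- vapply(seq_len(8000), function(i) {
    simulate_measurement(0, sig, inst)$absorbance[1]
  }, numeric(1))
  expect_equal(sd(vals), 0.02 / sqrt(16), tolerance = 0.04)
})

test_that("calibration sets keep their labels and sizes", {
  inst <- narrow_instrument()
  cs <- generate_calibration_set(seq(0.5, 3, by = 0.5), 5,
                                 default_api_signature(), inst, seed = 9)
  expect_length(cs$spectra, 30)
  expect_identical(cs$density, rep(seq(0.5, 3, by = 0.5), each = 5))
  expect_true(all(vapply(seq_along(cs$spectra),
                         function(i) cs$spectra[[i]]$true_density == cs$density[i],
                         logical(1))))
  expect_error(generate_calibration_set(numeric(0), 5, default_api_signature(), inst),
               class = "ftir_invalid_target")
})

test_that("noise-free replicates at equal levels are identical", {
  inst <- noise_free_instrument()
  cs <- generate_calibration_set(1.5, 3, default_api_signature(), inst, seed = 2)
  expect_identical(cs$spectra[[1]]$absorbance, cs$spectra[[2]]$absorbance)
  expect_identical(cs$spectra[[2]]$absorbance, cs$spectra[[3]]$absorbance)
})

test_that("pseudo-blank replicates share ground truth and baseline", {
  inst <- narrow_instrument()
  reps <- generate_pseudo_blank_replicates(0.3, 10, default_api_signature(),
                                           inst, seed = 3)
  expect_length(reps$spectra, 10)
  expect_true(all(reps$density == 0.3))
  # with zero noise the shared-baseline design makes replicates identical
  reps0 <- generate_pseudo_blank_replicates(0.3, 10, default_api_signature(),
                                            narrow_instrument(noise = 0), seed = 3)
  for (i in 2:10) {
    expect_identical(reps0$spectra[[i]]$absorbance, reps0$spectra[[1]]$absorbance)
  }
  expect_error(generate_pseudo_blank_replicates(0.3, 1, default_api_signature(), inst),
               class = "ftir_invalid_target")
})

test_that("simulation is bit-identical under a repeated seed", {
  inst <- narrow_instrument()
  a <- simulate_measurement(0.6, default_api_signature(), inst, seed = 77)
  b <- simulate_measurement(0.6, default_api_signature(), inst, seed = 77)
  expect_identical(a, b)
})

test_that("two-column text round-trips bit-exactly", {
  sp <- simulate_measurement(0.6, default_api_signature(),
                             narrow_instrument(), seed = 5)
  path <- withr::local_tempfile(fileext = ".txt")
  write_spectrum(sp, path)
  back <- read_spectrum(path)
  expect_identical(back$wavenumber, sp$wavenumber)
  expect_identical(back$absorbance, sp$absorbance)
})

test_that("jcamp-dx round-trips to its stated resolution", {
  sp <- simulate_measurement(0.6, default_api_signature(),
                             narrow_instrument(), seed = 6)
  path <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(sp, path, dialect = "jcamp-dx")
  back <- read_spectrum(path, dialect = "jcamp-dx")
  expect_equal(back$wavenumber, sp$wavenumber, tolerance = 1e-9)
  expect_lt(max(abs(back$absorbance - sp$absorbance)), 1e-8)
})

test_that("descending wavenumbers are re-sorted with a warning", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header", "1300 0.3", "1200 0.2", "1100 0.1"), path)
  expect_warning(sp <- read_spectrum(path), "descending")
  expect_identical(sp$wavenumber, c(1100, 1200, 1300))
  expect_identical(sp$absorbance, c(0.1, 0.2, 0.3))
})

test_that("malformed and truncated files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1100 0.1", "1200 not-a-number"), path)
  err <- expect_error(read_spectrum(path), class = "ftir_parse_error")
  expect_match(conditionMessage(err), "line 2")

  sp <- simulate_measurement(0.6, default_api_signature(),
                             narrow_instrument(), seed = 8)
  jdx <- withr::local_tempfile(fileext = ".jdx")
  write_spectrum(sp, jdx, dialect = "jcamp-dx")
  lines <- readLines(jdx)
  writeLines(lines[1:(length(lines) - 5)], jdx)
  expect_error(read_spectrum(jdx, dialect = "jcamp-dx"),
               class = "ftir_parse_error")
})
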