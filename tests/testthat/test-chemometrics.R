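# Window restriction, baseline correction, and the PLS calibration.

test_that("window restriction keeps exactly the channels inside each window", {
  sp <- ftir_spectrum(c(1000, 1200, 1250, 1300), c(1, 2, 3, 4))
  # full-range window is the identity
  full <- restrict_to_windows(sp, spectral_windows(c(1000, 1300)))
  expect_identical(full$wavenumber, sp$wavenumber)
  expect_identical(full$absorbance, sp$absorbance)
  # the narrow model window retains only the 1250 channel
  one <- restrict_to_windows(sp, spectral_windows(c(1200.20, 1259.84)))
  expect_identical(one$wavenumber, 1250)
  expect_identical(one$absorbance, 3)
  # closed interval at both endpoints
  closed <- restrict_to_windows(sp, spectral_windows(c(1200, 1250)))
  expect_identical(closed$wavenumber, c(1200, 1250))
})

test_that("two windows concatenate in order with summed lengths", {
  sp_full <- simulate_measurement(1, default_api_signature(),
                                  instrument_profile(noise_sd_per_scan = 0,
                                                     baseline_shift_sd = 0),
                                  seed = 1)
  w2 <- spectral_windows(list(c(1187.15, 1289.65), c(2884.96, 2993.05)))
  ch <- restrict_to_windows(sp_full, w2)
  n1 <- sum(ch$window == 1); n2 <- sum(ch$window == 2)
  expect_identical(length(ch$absorbance), n1 + n2)
  expect_true(all(diff(ch$wavenumber[ch$window == 1]) > 0))
  expect_true(all(diff(ch$wavenumber[ch$window == 2]) > 0))
  # coverage error when a window leaves the grid
  expect_error(restrict_to_windows(sp_full, spectral_windows(c(4100, 4200))),
               class = "ftir_window_coverage")
})

test_that("linear baseline correction removes offsets and tilts exactly", {
  wn <- seq(1200, 1260, by = 2)
  mk <- function(ab) list(wavenumber = wn, absorbance = ab,
                          window = rep(1L, length(wn)))
  expect_true(all(baseline_correct(mk(rep(0.37, length(wn))))$absorbance == 0))
  tilt <- 0.001 * wn - 0.9
  expect_equal(baseline_correct(mk(tilt))$absorbance,
               rep(0, length(wn)), tolerance = 1e-12)
  # Gaussian on a tilt: closed-form oracle = peak minus its endpoint chord
  peak <- 0.05 * exp(-(wn - 1230)^2 / (2 * 12^2))
  chord <- peak[1] + (peak[length(wn)] - peak[1]) *
    (wn - wn[1]) / (wn[length(wn)] - wn[1])
  got <- baseline_correct(mk(peak + tilt))$absorbance
  expect_equal(got, peak - chord, tolerance = 1e-12)
  expect_equal(got[1], 0)
  expect_equal(got[length(wn)], 0)
  # too few channels for a line
  expect_error(
    baseline_correct(list(wavenumber = c(1, 2), absorbance = c(1, 2),
                          window = c(1L, 1L))),
    class = "ftir_degenerate_window"
  )
})

test_that("rank-1 data is fit exactly by one component", {
  set.seed(13)
  x <- rnorm(8)
  X <- cbind(x, 0.5 * x, -2 * x, 0 * x + 0)
  X[, 4] <- 3 * x
  y <- 2.5 * x + 1
  cal <- as_calibration_set(X, y)
  m <- fit_pls(cal, 1)
  pred <- sweep(X, 2, m$x_mean) %*% m$coefficients + m$y_mean
  expect_equal(pred[, 1], y, tolerance = 1e-10)
})

test_that("full-component PLS equals the least-squares solution", {
  set.seed(29)
  for (rep in 1:20) {
    X <- matrix(rnorm(8 * 5), 8, 5)
    y <- rnorm(8)
    m <- fit_pls(as_calibration_set(X, y), 5)
    Xc <- sweep(X, 2, colMeans(X))
    b_ols <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))[, 1]
    expect_equal(unname(m$coefficients), unname(b_ols), tolerance = 1e-8)
  }
})

test_that("degenerate calibration inputs are rejected", {
  X <- matrix(rnorm(12), 4, 3)
  expect_error(fit_pls(as_calibration_set(X, rep(1, 4)), 1),
               class = "ftir_degenerate_data")
  expect_error(fit_pls(as_calibration_set(matrix(1, 4, 3), 1:4), 1),
               class = "ftir_degenerate_data")
  expect_error(fit_pls(as_calibration_set(X, 1:4), 5),
               class = "ftir_degenerate_data")
})

test_that("the training-mean spectrum predicts the mean response exactly", {
  inst <- narrow_instrument()
  cs <- generate_calibration_set(c(0.5, 1, 1.5, 2, 2.5, 3), 3,
                                 default_api_signature(), inst, seed = 17)
  cal <- build_calibration_set(cs, default_prep())
  m <- fit_pls(cal, 2)
  wn <- wavenumber_grid(inst)
  mean_ab <- Reduce(`+`, lapply(cs$spectra, `[[`, "absorbance")) / length(cs$spectra)
  pred <- predict(m, ftir_spectrum(wn, mean_ab))
  expect_equal(pred$density, mean(cal$y), tolerance = 1e-10)
})

test_that("a noise-free spectrum inside the trained range is recovered", {
  inst <- noise_free_instrument()
  cs <- generate_calibration_set(c(0.5, 1, 1.5, 2, 2.5, 3), 2,
                                 default_api_signature(), inst, seed = 19)
  m <- fit_pls(build_calibration_set(cs, default_prep()), 1)
  sp <- simulate_measurement(1.5, default_api_signature(), inst, seed = 23)
  pred <- predict(m, sp)
  expect_equal(pred$density, 1.5, tolerance = 1e-6)
  expect_false(pred$extrapolated)
})

test_that("prediction is invariant to a constant spectral offset", {
  inst <- narrow_instrument()
  cs <- generate_calibration_set(c(0.5, 1.5, 2.5), 3,
                                 default_api_signature(), inst, seed = 31)
  m <- fit_pls(build_calibration_set(cs, default_prep()), 2)
  sp <- simulate_measurement(1.2, default_api_signature(), inst, seed = 37)
  shifted <- ftir_spectrum(sp$wavenumber, sp$absorbance + 0.5)
  expect_equal(predict(m, sp)$density, predict(m, shifted)$density,
               tolerance = 1e-10)
})

test_that("training predictions are scale-equivariant in the response", {
  set.seed(41)
  X <- matrix(rnorm(10 * 6), 10, 6)
  y <- rowSums(X[, 1:2]) + rnorm(10, 0, 0.1)
  m1 <- fit_pls(as_calibration_set(X, y), 3)
  mk <- fit_pls(as_calibration_set(X, 7 * y), 3)
  p1 <- sweep(X, 2, m1$x_mean) %*% m1$coefficients + m1$y_mean
  pk <- sweep(X, 2, mk$x_mean) %*% mk$coefficients + mk$y_mean
  expect_equal(pk[, 1], 7 * p1[, 1], tolerance = 1e-8)
})

test_that("cross-validation recovers the latent rank", {
  # rank 1, noise free
  x <- seq(1, 6)
  X1 <- outer(rep(x, each = 2), c(1, -0.5, 2, 0.3))
  y1 <- rep(x, each = 2)
  cv1 <- choose_components_cv(as_calibration_set(X1, y1), 3, folds = 3, seed = 1)
  expect_identical(cv1$n_components, 1L)
  # rank 2: two orthogonal factors, both needed for y
  set.seed(43)
  lev <- 1:6
  a <- lev / 2 + c(0.8, -0.6, 0.4, -0.9, 0.5, -0.2)
  b <- lev - a
  v1 <- c(1, 1, 0, 0, 1, 0); v2 <- c(0, 0, 1, -1, 0, 1)
  X2 <- (outer(a, v1) + outer(b, v2))[rep(1:6, each = 2), ]
  X2 <- X2 + matrix(rnorm(length(X2), 0, 1e-4), nrow(X2))
  y2 <- rep(lev, each = 2)
  cv2 <- choose_components_cv(as_calibration_set(X2, y2), 4, folds = 3, seed = 1)
  expect_identical(cv2$n_components, 2L)
  # deterministic under a repeated seed
  cv2b <- choose_components_cv(as_calibration_set(X2, y2), 4, folds = 3, seed = 1)
  expect_identical(cv2, cv2b)
})

test_that("model serialization round-trips losslessly", {
  inst <- narrow_instrument()
  cs <- generate_calibration_set(c(0.6, 1.2, 1.8, 2.4, 3.0), 3,
                                 default_api_signature(), inst, seed = 47)
  m <- fit_pls(build_calibration_set(cs, default_prep()), 2)
  m$calibration_floor <- 0.4
  path <- withr::local_tempfile(fileext = ".json")
  write_pls_model(m, path)
  back <- read_pls_model(path)
  expect_equal(back$coefficients, m$coefficients, tolerance = 1e-12)
  expect_equal(back$x_mean, m$x_mean, tolerance = 1e-12)
  expect_identical(back$n_components, m$n_components)
  expect_equal(back$training_range, m$training_range, tolerance = 1e-12)
  expect_equal(back$calibration_floor, 0.4)
  expect_identical(back$prep$windows$windows, m$prep$windows$windows)
  # round-tripped model predicts identically
  sp <- simulate_measurement(1.1, default_api_signature(), inst, seed = 53)
  expect_equal(predict(back, sp)$density, predict(m, sp)$density,
               tolerance = 1e-10)
})
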