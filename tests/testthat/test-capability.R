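# Margin of error, CpK capability, and sample-size estimation.

# Independent t-quantile oracle: bisection on the incomplete-beta tail of
# the t CDF, P(T <= t) = 1 - pbeta(df/(df + t^2), df/2, 1/2)/2 for t >= 0.
t_quantile_oracle <- function(p, df) {
  stopifnot(p >= 0.5)
  cdf <- function(t) 1 - stats::pbeta(df / (df + t^2), df / 2, 0.5) / 2
  lo <- 0; hi <- 1e6
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (cdf(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("percent RSD matches the hand oracle and is scale invariant", {
  expect_equal(percent_rsd(c(1, 2, 3)), 50)
  expect_equal(percent_rsd(rep(0.6, 5)), 0)
  expect_equal(percent_rsd(7 * c(1, 2, 3)), 50, tolerance = 1e-12)
  expect_error(percent_rsd(1), class = "ftir_insufficient_sample")
  expect_error(percent_rsd(c(-1, 1)), class = "ftir_undefined_rsd")
})

test_that("t quantile agrees with the incomplete-beta bisection oracle", {
  expect_identical(t_quantile(0.5, 3), 0)
  expect_identical(t_quantile(0.5, 17), 0)
  for (df in 1:50) {
    for (p in c(0.9, 0.975, 0.99865)) {
      expect_equal(t_quantile(p, df), t_quantile_oracle(p, df),
                   tolerance = 1e-6)
    }
  }
  # symmetry and monotonicity
  expect_equal(t_quantile(0.1, 7), -t_quantile(0.9, 7), tolerance = 1e-12)
  expect_lt(t_quantile(0.9, 9), t_quantile(0.975, 9))
  # normal 3-sigma limit at large df
  expect_equal(t_quantile(0.99865, 1e6), 3.000, tolerance = 1e-3)
  expect_error(t_quantile(1.2, 5), class = "ftir_invalid_params")
  expect_error(t_quantile(0.9, 0), class = "ftir_invalid_params")
})

test_that("margin of error follows t * sd / sqrt(n)", {
  p <- moe_params()
  expect_identical(round(margin_of_error(10, p), 3), 0.388)
  expect_identical(margin_of_error(10, moe_params(sd = 0)), 0)
  expect_equal(margin_of_error(5, moe_params(mean = 0.6, sd = 1, confidence = 0.95)),
               t_quantile_oracle(0.975, 4) / sqrt(5), tolerance = 1e-6)
  expect_error(margin_of_error(1, p), class = "ftir_insufficient_sample")
})

test_that("the mean interval reproduces 0.212-0.988 at the defaults", {
  iv <- mean_interval(moe_params(), 10)
  expect_equal(round(iv$lower, 3), 0.212)
  expect_equal(round(iv$upper, 3), 0.988)
  expect_false(iv$floored)
  # degenerate sd
  iv0 <- mean_interval(moe_params(sd = 0), 10)
  expect_identical(c(iv0$lower, iv0$upper), c(0.6, 0.6))
  # large sd at small n: reported bound floored at zero, raw value kept
  ivf <- mean_interval(moe_params(sd = 0.5), 3)
  expect_identical(ivf$lower, 0)
  expect_lt(ivf$lower_raw, 0)
  expect_true(ivf$floored)
})

test_that("CpK arithmetic and classification bands are correct", {
  expect_equal(cpk(1, 0.6, 0.3), 0.4 / 0.9, tolerance = 1e-12)
  expect_identical(cpk(0.6, 0.6, 0.2), 0)
  expect_error(cpk(1, 0.6, 0), class = "ftir_invalid_params")
  expect_identical(classify_cpk(c(0.1, 1.5, 1.8, 2.5)),
                   c("Poor", "Acceptable", "Good", "Excellent"))
  # band edges: 1.33 and 1.67 are Acceptable, 2.00 is Good
  expect_identical(classify_cpk(c(1.33, 1.67, 2.00)),
                   c("Acceptable", "Acceptable", "Good"))
  expect_error(classify_cpk(Inf), class = "ftir_invalid_params")
})

test_that("the capability curve is monotone and internally consistent", {
  p <- moe_params()
  cc <- capability_curve(p, 15)
  expect_identical(cc$n, 2:15)
  expect_true(all(diff(cc$moe) < 0))
  expect_true(all(diff(cc$cpk) > 0))
  # interval symmetric about the mean wherever the floor is inactive
  expect_equal(cc$upper - p$mean, cc$moe, tolerance = 1e-12)
  unfloored <- cc$lower > 0
  expect_equal(p$mean - cc$lower[unfloored], cc$moe[unfloored],
               tolerance = 1e-12)
  # compositional oracle: each row equals the composed primitives
  for (i in seq_len(nrow(cc))) {
    expect_equal(cc$cpk[i], cpk(p$ral, p$mean, margin_of_error(cc$n[i], p)),
                 tolerance = 1e-12)
  }
  one <- capability_curve(p, 2)
  expect_identical(nrow(one), 1L)
})

test_that("MOE grows with sd and confidence, shrinks with n", {
  n <- c(5, 10, 20)
  expect_true(all(diff(margin_of_error(n, moe_params())) < 0))
  expect_lt(margin_of_error(10, moe_params(sd = 0.2)),
            margin_of_error(10, moe_params(sd = 0.3)))
  expect_lt(margin_of_error(10, moe_params(confidence = 0.95)),
            margin_of_error(10, moe_params(confidence = 0.9973)))
})

test_that("minimum sample size is monotone in the target CpK", {
  p <- moe_params()
  expect_identical(min_samples_for_cpk(0, p)$n, 2L)
  # a target below the n = 2 capability is met immediately
  low <- cpk(p$ral, p$mean, margin_of_error(2, p)) / 2
  expect_identical(min_samples_for_cpk(low, p)$n, 2L)
  targets <- c(0.2, 0.5, 1.0, 1.33, 1.67)
  ns <- vapply(targets, function(t) min_samples_for_cpk(t, p, n_cap = 500)$n,
               integer(1))
  expect_true(all(diff(ns) >= 0))
  # unreachable under a small cap
  res <- min_samples_for_cpk(1.67, p, n_cap = 20)
  expect_false(res$achievable)
  expect_true(is.na(res$n))
})

test_that("reported 7/10-sample claims are flagged as a discrepancy", {
  expect_message(
    out <- compare_reported_sample_sizes(moe_params()),
    "not reproducible"
  )
  expect_false(any(out$agrees))
  expect_match(attr(out, "note"), "Discrepancy")
  # the computed minima match the scan primitive
  expect_identical(out$computed_n[1], min_samples_for_cpk(1.33, moe_params())$n)
  expect_identical(out$computed_n[2], min_samples_for_cpk(1.67, moe_params())$n)
})
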