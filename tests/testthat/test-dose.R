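test_that("exact Hill data are recovered and the EC50 response is half-maximal", {
  conc <- 10^seq(-2, 2, by = 0.5)
  resp <- conc / (conc + 1)
  f <- fit_dose_response(conc, resp)
  expect_equal(f$ec50, 1, tolerance = 1e-6)
  expect_equal(f$hill, 1, tolerance = 1e-6)
  expect_equal(predict(f, f$ec50), (f$top + f$bottom) / 2, tolerance = 1e-9)
})

test_that("non-spanning dose data are flagged as extrapolated", {
  conc <- c(10, 20, 40, 80, 160)
  resp <- conc / (conc + 0.5)  # EC50 far below the measured range
  f <- fit_dose_response(conc, resp)
  expect_true(f$extrapolated)
})

test_that("sigmoid half-time fit: exact midpoint, shift equivariance, noise robustness", {
  t <- seq(0, 30, by = 3)
  y <- 1 / (1 + exp(-(t - 12) / 2))
  expect_equal(fit_t50(t, y)$t50, 12, tolerance = 1e-6)

  y5 <- 1 / (1 + exp(-(t - 17) / 2))
  expect_equal(fit_t50(t, y5)$t50 - fit_t50(t, y)$t50, 5, tolerance = 1e-6)

  # noisy recovery at 0.33 Hz sampling, noise SD 5% of the range
  set.seed(42)
  tt <- seq(0, 36, by = 3)
  errs <- vapply(1:20, function(i) {
    yy <- 1 / (1 + exp(-(tt - 12) / 2)) + rnorm(length(tt), 0, 0.05)
    abs(fit_t50(tt, yy)$t50 - 12)
  }, numeric(1))
  expect_lt(mean(errs), 1)
})

test_that("synthetic occupancy dose series recovers the published agonist EC50", {
  dr <- dose_response_series("oxom_dose", n_cells = 3, seed = 5)
  expect_equal(dr$fit$ec50, 0.112, tolerance = 0.25)
  expect_false(dr$fit$extrapolated)
  # responses rise monotonically (up to noise) across the series
  expect_gt(cor(log(dr$series$conc), dr$series$response), 0.9)
})
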