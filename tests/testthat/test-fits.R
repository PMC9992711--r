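test_that("two-step decomposition recovers a noiseless biexponential within 2%", {
  t <- seq(0, 15, 0.1)
  y <- 0.5 * exp(-t / 0.2) + 0.5 * exp(-t / 2.0)
  f <- fit_two_step(make_norm_trace(t, y), mode = "ON")
  expect_equal(f$tau1, 0.2, tolerance = 0.02)
  expect_equal(f$tau2, 2.0, tolerance = 0.02)
})

test_that("windowed fit bias is below 2% across the time-constant grid", {
  t <- seq(0, 15, 0.1)
  for (tau1 in c(0.1, 0.3, 0.5)) {
    for (tau2 in c(1, 2.5, 4)) {
      y <- 0.5 * exp(-t / tau1) + 0.5 * exp(-t / tau2)
      f <- fit_two_step(make_norm_trace(t, y), mode = "ON")
      expect_equal(f$tau1, tau1, tolerance = 0.02,
                   label = sprintf("tau1 at (%g, %g)", tau1, tau2))
      expect_equal(f$tau2, tau2, tolerance = 0.02,
                   label = sprintf("tau2 at (%g, %g)", tau1, tau2))
    }
  }
})

test_that("a pure single exponential leaves no material step-2 amplitude", {
  t <- seq(0, 15, 0.1)
  y <- exp(-t / 0.2)
  f <- fit_two_step(make_norm_trace(t, y), mode = "ON")
  expect_lt(f$amp2, 0.01 * (f$amp1 + f$amp2))
})

test_that("single-step fit recovers tau, injected delay and flags flat traces", {
  t <- seq(0, 30, 0.1)
  y <- 1 - 0.25 * (1 - exp(-t / 1.45))
  f <- fit_single_step(make_norm_trace(t, y, agonist_on = 0), mode = "ON")
  expect_equal(f$tau1, 1.45, tolerance = 0.01)

  yd <- 1 - 0.25 * (t > 0.25) * (1 - exp(-pmax(t - 0.25, 0) / 1.45))
  fd <- fit_single_step(make_norm_trace(t, yd, agonist_on = 0), mode = "ON")
  expect_equal(fd$delay, 0.25, tolerance = 0.1)  # within one 10 Hz sample
  expect_equal(fd$tau1, 1.45, tolerance = 0.02)

  set.seed(11)
  tt <- seq(0, 40, 0.1)
  flat <- 1 + rnorm(length(tt), 0, 0.01)
  ff <- fit_single_step(make_norm_trace(tt, flat, agonist_on = 10),
                        mode = "ON")
  expect_true(ff$unidentifiable)
  expect_lt(ff$amp1, 0.05)
})

test_that("OFF-mode fits anchor at the washout mark", {
  t <- seq(0, 60, 0.1)
  y <- ifelse(t < 30, 0, 1 - exp(-(t - 30) / 0.53))
  f <- fit_single_step(make_norm_trace(t, y, agonist_on = 5,
                                       agonist_off = 30), mode = "OFF")
  expect_equal(f$tau1, 0.53, tolerance = 0.01)
  expect_error(fit_single_step(make_norm_trace(t, y, agonist_on = 5),
                               mode = "OFF"), "mark")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  t <- seq(0, 15, 0.1)
  y <- chain_biexp(0.22, 1.92, t)
  f <- fit_two_step(make_norm_trace(t, y), mode = "ON")
  cf <- coef(f)
  expect_named(cf, c("delay", "tau1", "amp1", "tau2", "amp2"))
  pr <- predict(f)
  inw <- !is.na(pr$value)
  expect_gt(sum(inw), 100)
  expect_lt(max(abs(pr$value[inw] - y[inw])), 0.01)
  expect_lt(max(abs(residuals(f)[inw])), 0.01)
})
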