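test_that("reciprocal calibration inverts the target time constants", {
  tg <- macroscopic_targets(tau1_on = 0.22, tau2_on = 1.92,
                            tau1_off = 0.47, tau2_off = 20)
  r <- calibrate_rates(tg, mode = "reciprocal")
  expect_equal(r$k_couple, 4.5455, tolerance = 1e-4)
  expect_equal(r$k_exch, 1 / 1.92)
  expect_equal(r$k_bg_off, 1 / 0.47)
  expect_equal(r$k_hyd, 0.05)
})

test_that("refined calibration closes the loop: pipeline-fitted taus hit the targets", {
  tg <- macroscopic_targets()
  r <- calibrate_rates(tg, mode = "refined", tol = 0.05, maxit = 60)
  taus <- gqfret:::.pipeline_taus(r)
  goal <- c(tg$tau1_on, tg$tau2_on, tg$tau1_off, tg$tau2_off)
  expect_true(all(abs(taus - goal) / goal < 0.05))
})

test_that("invalid macroscopic targets are rejected", {
  expect_error(macroscopic_targets(tau1_on = -1), "positive")
  expect_error(macroscopic_targets(step1_fraction = 1.2), "step1_fraction")
})
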