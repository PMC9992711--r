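test_that("sequential-chain solution satisfies initial condition and mass balance", {
  out <- closed_form_chain(3, 0.7, c(0, 0.1, 1, 10))
  expect_equal(unname(out[1, ]), c(1, 0, 0))
  expect_equal(unname(rowSums(out)), rep(1, 4), tolerance = 1e-12)
  expect_true(all(out >= 0))
})

test_that("repeated-root limit is the textbook k*t*exp(-k*t) and is continuous", {
  k <- 2.4
  t <- c(0.1, 0.5, 2)
  out <- closed_form_chain(k, k, t)
  expect_equal(unname(out[, "fracB"]), k * t * exp(-k * t), tolerance = 1e-12)
  near <- closed_form_chain(k, k * (1 + 1e-7), t)
  expect_equal(unname(near[, "fracB"]), unname(out[, "fracB"]),
               tolerance = 1e-6)
})

test_that("closed form matches brute-force RK4 integration of the chain", {
  k1 <- 1 / 0.22; k2 <- 1 / 1.92
  for (tt in c(0.5, 2, 5)) {
    ref <- rk4_chain(k1, k2, tt)
    got <- closed_form_chain(k1, k2, tt)
    expect_equal(unname(got[1, ]), ref, tolerance = 1e-6)
  }
})

test_that("invalid chain inputs are rejected", {
  expect_error(closed_form_chain(-1, 1, 0), "positive")
  expect_error(closed_form_chain(1, Inf, 0), "positive")
  expect_error(closed_form_chain(1, 1, -0.1), "non-negative")
})
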