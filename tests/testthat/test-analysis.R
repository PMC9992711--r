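test_that("FRET ratio formula and its edge cases", {
  ch <- list(t = 0:2, CFPc = c(1, 1, 1), YFPc = c(1.45, 1.45, 1.45),
             agonist_on = 0, agonist_off = NA_real_)
  expect_equal(compute_fretr(ch, cFactor = 0.45)$fretr, rep(1, 3))
  expect_equal(compute_fretr(ch, cFactor = 0)$fretr, rep(1.45, 3))
  ch$CFPc[2] <- 0
  expect_error(compute_fretr(ch, cFactor = 0.45), "index 2")
})

test_that("normalization pins both window means and is idempotent", {
  t <- seq(0, 60, 0.1)
  y <- 1.3 - 0.4 * (t > 10) * (1 - exp(-(t - 10) / 2))
  tr <- fretr_trace(t, y, agonist_on = 10, agonist_off = 45)
  nt <- normalize_trace(tr, "decrease")
  expect_equal(mean(nt$value[t >= 5 & t < 10]), 1, tolerance = 1e-9)
  expect_equal(mean(nt$value[t >= 40 & t < 45]), 0, tolerance = 1e-9)
  again <- normalize_trace(nt, "decrease")
  expect_equal(again$value, nt$value, tolerance = 1e-9)

  up <- fretr_trace(t, 2.6 - y, agonist_on = 10, agonist_off = 45)
  ntu <- normalize_trace(up, "increase")
  expect_equal(mean(ntu$value[t >= 5 & t < 10]), 1, tolerance = 1e-9)
  expect_equal(mean(ntu$value[t >= 40 & t < 45]), 2, tolerance = 1e-9)
})

test_that("degenerate and truncated traces are rejected", {
  t <- seq(0, 60, 0.1)
  flat <- fretr_trace(t, rep(1.2, length(t)), agonist_on = 10,
                      agonist_off = 45)
  expect_error(normalize_trace(flat, "decrease"), "degenerate")
  short <- fretr_trace(seq(0, 3, 0.1), rnorm(31), agonist_on = 2)
  expect_error(normalize_trace(short, "decrease"), "baseline")
})

test_that("a linear ramp maps its window endpoints exactly", {
  # ramp from 1 to 0 whose two 5-s windows average 1 and 0
  t <- seq(0, 30, 0.1)
  y <- approx(c(0, 7.5, 22.5, 30), c(1, 1, 0, 0), xout = t)$y
  tr <- fretr_trace(t, y, agonist_on = 10, agonist_off = 25)
  # shift marks so windows sit on the flat stretches
  tr$agonist_on <- 7.5; tr$agonist_off <- 27.5
  nt <- normalize_trace(tr, "decrease")
  expect_equal(nt$value[1], 1, tolerance = 1e-9)
  expect_equal(nt$value[length(t)], 0, tolerance = 1e-9)
})
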