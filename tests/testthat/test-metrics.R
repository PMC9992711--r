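test_that("SNR is amplitude over baseline standard error", {
  # baseline of known SD 0.1 over 50 samples -> SE 0.1/sqrt(50)
  base <- rep(c(-0.1, 0.1), 25) * sqrt(50 / 49)  # sample SD exactly 0.1...
  base <- base - mean(base)
  t <- seq(0, 14.9, 0.1)
  y <- c(1 + base, 1 - rep(1.0, 100))  # amplitude 1.0 response
  tr <- fretr_trace(t, y, agonist_on = 5)
  s <- compute_snr(tr, se_mode = "sem")
  expect_equal(s$snr, s$amplitude / (sd(1 + base) / sqrt(50)),
               tolerance = 1e-12)
  expect_equal(s$n_baseline, 50)
  s2 <- compute_snr(tr, se_mode = "sd")
  expect_equal(s2$snr * sqrt(50), s$snr, tolerance = 1e-12)

  flat <- fretr_trace(t, rep(1, length(t)), agonist_on = 5)
  sf <- compute_snr(flat)
  expect_true(is.infinite(sf$snr) && sf$degenerate)
})

test_that("percent metrics reproduce hand-computed ratios", {
  f <- structure(list(kind = "two_step", mode = "ON", amp1 = 0.3,
                      amp2 = 0.1, tau1 = 0.2, tau2 = 2),
                 class = "fret_fit")
  p <- percent_metrics(f, "two_step_on", max_amp = 0.4)
  expect_equal(p$pct_step1_on, 75)
  expect_equal(p$pct_step2_on, 25)
  expect_equal(p$remainder, 0)

  # default denominator is the summed fitted amplitude
  p2 <- percent_metrics(f, "two_step_on")
  expect_equal(p2$pct_step1_on, 75)

  off <- structure(list(kind = "single_step", mode = "OFF", amp1 = 0.4),
                   class = "fret_fit")
  expect_equal(percent_metrics(off, "single_step_off", max_amp = 0.4)$pct_off,
               100)
  expect_error(percent_metrics(off, "single_step_off", max_amp = 0),
               "zero maximum")
})

test_that("group-referenced single-step percentage follows the quoted formula", {
  t <- seq(0, 40, 0.1)
  cell <- make_norm_trace(t, 1 - 0.3 * (t > 10), agonist_on = 10,
                          agonist_off = 35)
  grp <- make_norm_trace(t, 1 - 0.4 * (t > 10), agonist_on = 10,
                         agonist_off = 35)
  p <- percent_metrics(cell, "single_step_on", group_trace = grp)
  expect_equal(p$pct_on, 100 * 0.3 / 0.4)
  expect_error(percent_metrics(cell, "single_step_on"), "group-average")
})

test_that("summaries report mean, SEM = sd/sqrt(n) and n", {
  vals <- c(1, 2, 3, 4)
  s <- summarize_fits(list(), condition = "x", extra = list(m = vals))
  expect_equal(s$mean, 2.5)
  expect_equal(s$sem, sd(vals) / 2)
  expect_equal(s$n, 4)
  same <- summarize_fits(list(), extra = list(m = rep(3, 5)))
  expect_equal(same$sem, 0)
  one <- summarize_fits(list(), extra = list(m = 7))
  expect_true(is.na(one$sem))
})
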