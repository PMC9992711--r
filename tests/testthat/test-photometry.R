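test_that("ratio computation exactly inverts the noiseless renderer", {
  t <- seq(0, 20, 0.1)
  r <- 1.2 - 0.3 * (1 - exp(-t / 2))
  tr <- fretr_trace(t, r, agonist_on = 0)
  # bleach-free
  ch <- render_channels(tr, optics_spec(donor_base = 50))
  expect_equal(compute_fretr(ch)$fretr, r, tolerance = 1e-9)
  # shared photobleaching cancels in the ratio
  ch2 <- render_channels(tr, optics_spec(donor_base = 50, bleach_rate = 0.01))
  expect_equal(compute_fretr(ch2)$fretr, r, tolerance = 1e-9)
})

test_that("renderer follows the generative ratio formula", {
  t <- seq(0, 5, 0.5)
  tr <- fretr_trace(t, rep(1, length(t)), agonist_on = 0)
  ch <- render_channels(tr, optics_spec(cFactor = 0.45, donor_base = 1))
  expect_equal(ch$CFPc, rep(1, length(t)))
  expect_equal(ch$YFPc, rep(1.45, length(t)))
})

test_that("cell generation is deterministic and honours the jitter contract", {
  d1 <- tempfile(); d2 <- tempfile()
  ds1 <- generate_cells("wt_gtp", 3, seed = 42)
  ds2 <- generate_cells("wt_gtp", 3, seed = 42)
  write_cells(ds1, d1); write_cells(ds2, d2)
  expect_identical(readBin(file.path(d1, "traces.csv"), "raw", 1e7),
                   readBin(file.path(d2, "traces.csv"), "raw", 1e7))

  # no jitter + no noise => identical cells
  ds0 <- generate_cells("wt_gtp", 3, seed = 7, noise_scale = 0,
                        jitter_cv = 0)
  expect_equal(ds0$cells[[1]]$YFPc, ds0$cells[[2]]$YFPc)
  expect_equal(ds0$cells[[2]]$CFPc, ds0$cells[[3]]$CFPc)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("trace table dimensions follow the protocol grid", {
  proto <- stimulus_protocol(45, hz = 10, agonist_on = 10, agonist_off = 40)
  ds <- generate_cells("wt_gtp", 4, seed = 1, protocol = proto)
  d <- tempfile()
  write_cells(ds, d)
  tab <- read_cells(d)$traces
  expect_equal(nrow(tab), 4 * 451)
  expect_equal(length(unique(tab$cell_id)), 4)
  unlink(d, recursive = TRUE)
})

test_that("CSV round trip preserves the channel data", {
  ds <- generate_cells("rgbg_gtp", 2, seed = 3)
  d <- tempfile()
  write_cells(ds, d)
  back <- read_cells(d)
  c1 <- back$traces[back$traces$cell_id == "cell_001", ]
  expect_equal(c1$cfp_c, ds$cells[[1]]$CFPc, tolerance = 1e-12)
  expect_equal(back$ground_truth$preset, "rgbg_gtp")
  unlink(d, recursive = TRUE)
})

test_that("doubling channel noise halves the expected pipeline SNR", {
  x <- noiseless_trace("wt_gtp")
  optics <- x$preset$optics
  n_base <- round(5 * x$preset$protocol$hz)
  amp <- abs(gqfret:::.pair_amplitude(x$preset$pair))
  sd1 <- noise_for_snr(x$preset$snr, amp, x$preset$pair$baseline_fretr,
                       optics, n_base)
  snr_mc <- function(sd_ch, n = 200) {
    vapply(seq_len(n), function(i) {
      o <- optics
      o$noise_sd_donor <- sd_ch; o$noise_sd_acceptor <- sd_ch
      ch <- render_channels(x$fretr, o, seed = 1000 + i)
      compute_snr(compute_fretr(ch))$snr
    }, numeric(1))
  }
  m1 <- mean(snr_mc(sd1))
  m2 <- mean(snr_mc(2 * sd1))
  expect_equal(m1 / m2, 2, tolerance = 0.1)
  # calibration check: mean pipeline SNR is near the preset target; the
  # max-statistic bias over ~700 response samples keeps it slightly high
  expect_equal(m1, x$preset$snr, tolerance = 0.2)
})
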