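trans_rate <- function(net, from, to) {
  for (tr in net$transitions)
    if (tr$from == from && tr$to == to) return(tr$rate)
  NA_real_
}

test_that("condition modifiers reshape the network as the scheme dictates", {
  r <- rate_set()
  wt <- build_network(condition_spec(), r)
  expect_gt(trans_rate(wt, "RLG", "RLSep"), 0)
  expect_equal(trans_rate(wt, "RLG", "RLSep"), r$k_exch)

  gdp <- build_network(condition_spec(nucleotide = "GDPbetaS"), r,
                       gdpbs_factor = 0.2)
  expect_equal(trans_rate(gdp, "RLG", "RLSep"), r$k_exch * 0.2)

  # coupling-dead receptor: no route from RL toward any G-bound state
  ta <- build_network(condition_spec(receptor_variant = "TripleA"), r)
  expect_equal(trans_rate(ta, "RL", "RLG"), 0)
  expect_true(is.na(trans_rate(ta, "RL", "RLSep")))

  # constitutively active Galpha: pre-separated pool, single-step route,
  # no hydrolysis
  q <- build_network(condition_spec(galpha_variant = "Q209L"), r)
  expect_equal(trans_rate(q, "RL", "RLSep"), r$k_couple)
  expect_true(is.na(trans_rate(q, "RL", "RLG")))
  expect_equal(q$rates$k_hyd, 0)

  expect_error(build_network(condition_spec(), r, gdpbs_factor = -1))
})

test_that("integration conserves occupancy and starts in the resting state", {
  proto <- stimulus_protocol(40, hz = 10, agonist_on = 10, agonist_off = 30)
  for (nm in c("wt_gtp", "q209l", "wt_gdpbs", "triple_a")) {
    p <- get_preset(nm)
    net <- build_network(p$condition, p$rates)
    traj <- integrate_network(net, proto)
    expect_equal(unname(traj$occupancy[1, "R"]), 1)
    expect_true(all(abs(rowSums(traj$occupancy) - 1) < 1e-8),
                label = paste("conservation for", nm))
    expect_true(all(traj$occupancy >= 0 & traj$occupancy <= 1),
                label = paste("occupancy bounds for", nm))
  }
})

test_that("integrator matches the closed-form chain oracle to 1e-6", {
  # near-instant agonist binding isolates the RL -> RLG -> RLSep subchain
  r <- rate_set(k_L_on = 1e8, k_L_off = 0, k_plc_on = 0)
  net <- build_network(condition_spec(), r)
  proto <- stimulus_protocol(15, hz = 10, agonist_on = 0.0,
                             agonist_off = NULL, conc = 10,
                             exchange_tau = 0)
  traj <- integrate_network(net, proto)
  ref <- closed_form_chain(r$k_couple, r$k_exch, traj$t)
  expect_equal(unname(traj$occupancy[, "R"] + traj$occupancy[, "RL"]),
               unname(ref[, "fracA"]), tolerance = 1e-6)
  expect_equal(unname(traj$occupancy[, "RLG"]), unname(ref[, "fracB"]),
               tolerance = 1e-6)
  expect_equal(unname(traj$occupancy[, "RLSep"]), unname(ref[, "fracC"]),
               tolerance = 1e-6)
})

test_that("kinetic ordering holds: coupling precedes separation; Gbg leaves before Ga", {
  x <- noiseless_trace("wt_gtp")
  occ <- x$traj$occupancy
  t <- x$traj$t
  half_time <- function(v) t[which(v >= max(v) / 2)[1]]
  expect_lt(half_time(occ[, "RLG"]), half_time(occ[, "RLSep"]))

  off <- x$preset$protocol$agonist_off
  post <- t > off + 0.5
  gbg_bound <- rowSums(occ[, c("RLG", "RLSep", "RLSepPLC")])
  ga_bound <- rowSums(occ[, c("RLG", "RLSep", "RLSepPLC", "RGa", "RGaPLC")])
  decay_time <- function(v) {
    vv <- v[post]
    t[post][which(vv <= vv[1] / 2)[1]]
  }
  expect_lt(decay_time(gbg_bound), decay_time(ga_bound))
})

test_that("perturbation logic: YM, coupling-dead and pre-separated presets", {
  # YM held: separation never happens
  ym <- noiseless_trace("wt_ym_hold")
  expect_lt(max(ym$traj$occupancy[, "RLSep"]), 1e-10)

  # coupling-dead: no G-bound occupancy at all
  ta <- noiseless_trace("triple_a")
  gstates <- c("RLG", "RLGb", "RLSep", "RLSepPLC", "RGa", "RGaPLC")
  expect_lt(max(ta$traj$occupancy[, gstates]), 1e-12)

  # constitutively active mutant: never passes through the trimer state,
  # and carries no slow OFF component (full recovery within ~5 fast
  # time constants of washout)
  q <- noiseless_trace("q209l")
  expect_lt(max(q$traj$occupancy[, "RLG"]), 1e-12)
  off <- q$preset$protocol$agonist_off
  late <- q$traj$t > off + 5 * 0.47
  active <- rowSums(q$traj$occupancy[, gstates])
  expect_lt(max(active[late]), 0.01)
})

test_that("YM washout releases the configured fraction of blocked complexes", {
  p <- get_preset("wt_ym_washout")
  net <- build_network(p$condition, p$rates, ym_unblocked = 0.31)
  traj <- integrate_network(net, p$protocol)
  occ <- traj$occupancy
  # blocked species retains ~69% of what was coupled when YM left at 20 s
  i20 <- which.min(abs(traj$t - 20))
  rlg_at_washout <- occ[i20, "RLG"] + occ[i20, "RLGb"]
  expect_equal(unname(occ[nrow(occ), "RLGb"]),
               unname(0.69 * rlg_at_washout), tolerance = 0.02)
  # separated occupancy eventually appears, but stays bounded by the
  # unblocked fraction of the pool
  sep_max <- max(occ[, "RLSep"] + occ[, "RLSepPLC"])
  expect_gt(sep_max, 0.1)
  expect_lt(sep_max, 0.45)
})
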