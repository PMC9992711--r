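# Shared fixtures built in code.

# Brute-force RK4 integration of the irreversible chain A -> B -> C,
# independent of the package's propagator and of closed_form_chain.
rk4_chain <- function(k1, k2, t_end, dt = 1e-4) {
  f <- function(x) c(-k1 * x[1], k1 * x[1] - k2 * x[2], k2 * x[2])
  x <- c(1, 0, 0)
  n <- ceiling(t_end / dt)
  h <- t_end / n
  for (i in seq_len(n)) {
    s1 <- f(x); s2 <- f(x + h / 2 * s1); s3 <- f(x + h / 2 * s2)
    s4 <- f(x + h * s3)
    x <- x + h / 6 * (s1 + 2 * s2 + 2 * s3 + s4)
  }
  x
}

# A normalized_trace built directly from values on a grid (bypasses the
# normalization step for fit-level tests).
make_norm_trace <- function(t, value, agonist_on = 0,
                            agonist_off = NA_real_,
                            direction = "decrease") {
  structure(list(t = t, value = value, direction = direction,
                 agonist_on = agonist_on, agonist_off = agonist_off,
                 baseline_window = 5, plateau_window = 5),
            class = "normalized_trace")
}

# Normalized two-step activation trace of the sequential chain with a
# 50/50 coefficient split: value = fracA + 0.5 * fracB (1 -> 0).
chain_biexp <- function(tau1, tau2, t) {
  k1 <- 1 / tau1; k2 <- 1 / tau2
  occ <- closed_form_chain(k1, k2, t)
  occ[, "fracA"] + 0.5 * occ[, "fracB"]
}

# Noiseless single-cell trace for a preset (no jitter, no noise).
noiseless_trace <- function(preset_name) {
  p <- get_preset(preset_name)
  net <- build_network(p$condition, p$rates,
                       gdpbs_factor = p$gdpbs_factor,
                       ym_unblocked = p$ym_unblocked)
  traj <- integrate_network(net, p$protocol)
  list(preset = p, traj = traj, fretr = true_fretr(traj, p$pair))
}
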