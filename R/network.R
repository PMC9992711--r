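# Species of the lumped receptor-Gq cycle:
#   R        unliganded receptor (G pool at rest; pre-assembled or
#            pre-separated depending on condition)
#   RL       liganded, uncoupled receptor
#   RLG      liganded receptor holding the intact heterotrimer
#   RLGb     YM-blocked RLG (absorbing; only present with a YM schedule)
#   RLSep    liganded receptor with separated Galpha-GTP and Gbetagamma
#            both still receptor-associated
#   RLSepPLC RLSep with PLCbeta recruited
#   RGa      post-washout receptor still holding Galpha-GTP (no Gbetagamma)
#   RGaPLC   RGa with PLCbeta still bound
.GQ_SPECIES <- c("R", "RL", "RLG", "RLGb", "RLSep", "RLSepPLC",
                 "RGa", "RGaPLC")

#' Build the condition-dependent receptor-Gq reaction network
#'
#' Assembles the lumped first-order scheme with the condition's
#' perturbations applied:
#' \itemize{
#'   \item GDP-beta-S multiplies the exchange rate `k_exch` by
#'     `gdpbs_factor` (default 1/5, the printed ~5x slowing of step 2);
#'   \item YM-254890 intervals force the exchange flux to zero while
#'     active; at each interval end only `ym_unblocked` of the accumulated
#'     coupled complex is released to proceed (the remainder is moved into
#'     an absorbing blocked species);
#'   \item GTP-gamma-S and the constitutively active Galpha mutants
#'     (Q209L, R183C) pre-separate the G pool: activation becomes a single
#'     `RL -> RLSep` step at `k_couple`, hydrolysis is disabled, and
#'     deactivation returns `RLSep -> R` at `k_bg_off`;
#'   \item the coupling-dead receptor mutants (TripleA, R166L) force
#'     `k_couple = 0`.
#' }
#' Rate expressions are gated by the stimulus: transitions tagged `"on"`
#' scale with the solution-exchange-filtered agonist presence \eqn{s(t)},
#' `"off"` transitions with \eqn{1 - s(t)}, the binding transition with
#' the filtered concentration \eqn{L(t)}, and `"always"` transitions are
#' ungated.
#'
#' @param condition A [condition_spec()].
#' @param rates A [rate_set()].
#' @param gdpbs_factor Multiplicative slowdown of `k_exch` under
#'   GDP-beta-S.
#' @param ym_unblocked Fraction of YM-blocked complexes released on YM
#'   washout.
#' @return An object of class `reaction_network`.
#' @export
build_network <- function(condition, rates, gdpbs_factor = 0.2,
                          ym_unblocked = 0.31) {
  stopifnot(inherits(condition, "condition_spec"), inherits(rates, "rate_set"))
  if (gdpbs_factor < 0 || ym_unblocked < 0 || ym_unblocked > 1)
    stop("build_network: gdpbs_factor must be >= 0 and ym_unblocked in [0, 1]")
  eff <- rates
  if (condition$nucleotide == "GDPbetaS")
    eff$k_exch <- eff$k_exch * gdpbs_factor
  pre_separated <- condition$nucleotide == "GTPgammaS" ||
    condition$galpha_variant %in% c("Q209L", "R183C")
  if (pre_separated) eff$k_hyd <- 0
  if (condition$receptor_variant %in% c("TripleA", "R166L"))
    eff$k_couple <- 0
  bad <- vapply(eff[1:8], function(v) !is.finite(v) || v < 0, logical(1))
  if (any(bad))
    stop("build_network: condition modifiers produced an invalid rate: ",
         paste(names(eff)[1:8][bad], collapse = ", "))

  tr <- list(
    list(from = "R", to = "RL", rate = eff$k_L_on, gate = "ligand"),
    list(from = "RL", to = "R", rate = eff$k_L_off, gate = "always"))
  add <- function(from, to, rate, gate)
    tr[[length(tr) + 1L]] <<- list(from = from, to = to, rate = rate,
                                   gate = gate)
  if (pre_separated) {
    add("RL", "RLSep", eff$k_couple, "on")
    add("RLSep", "R", eff$k_bg_off, "off")
  } else {
    add("RL", "RLG", eff$k_couple, "on")
    add("RLG", "RLSep", eff$k_exch, "exch")
    add("RLG", "R", eff$k_bg_off, "off")
    add("RLSep", "RGa", eff$k_bg_off, "off")
    add("RGa", "R", eff$k_hyd, "always")
  }
  if (eff$k_plc_on > 0) {
    add("RLSep", "RLSepPLC", eff$k_plc_on, "on")
    add("RLSepPLC", "RGaPLC", eff$k_bg_off, "off")
    add("RGaPLC", "RGa", eff$k_plc_off, "always")
  }
  structure(list(species = .GQ_SPECIES, transitions = tr,
                 condition = condition, rates = eff,
                 pre_separated = pre_separated,
                 ym_schedule = condition$ym_schedule,
                 ym_unblocked = ym_unblocked),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Receptor-Gq reaction network (", length(x$transitions),
      " transitions)\n", sep = "")
  for (tr in x$transitions)
    cat(sprintf("  %-9s -> %-9s %.4g  [%s]\n", tr$from, tr$to, tr$rate,
                tr$gate))
  if (x$pre_separated) cat("  (pre-separated G pool at rest)\n")
  invisible(x)
}

#' Piecewise-constant stimulus protocol with solution-exchange filtering
#'
#' Describes the agonist schedule of a recording: baseline, an agonist
#' application of `conc` micromolar between `agonist_on` and
#' `agonist_off`, then washout until `duration`. Concentration steps are
#' low-pass filtered with time constant `exchange_tau`, emulating the
#' theta-tube solution exchange that completes within ~20 ms (default
#' `0.02/3` s, i.e. 95% complete at 20 ms).
#'
#' @param duration Total recording length in seconds.
#' @param hz Sampling frequency (1, 10 or 100 Hz in the experiments; any
#'   positive value is accepted).
#' @param agonist_on,agonist_off Agonist application marks in seconds;
#'   `agonist_off = NULL` keeps the agonist on until the end.
#' @param conc Agonist concentration in micromolar.
#' @param exchange_tau Exchange filter time constant in seconds (0
#'   disables filtering).
#' @return An object of class `stimulus_protocol` with the sample grid in
#'   `$t` and segment table in `$segments`.
#' @export
stimulus_protocol <- function(duration, hz = 10, agonist_on,
                              agonist_off = NULL, conc = 10,
                              exchange_tau = 0.02 / 3) {
  if (duration <= 0 || hz <= 0 || exchange_tau < 0)
    stop("stimulus_protocol: duration and hz must be positive, exchange_tau >= 0")
  if (agonist_on < 0 || agonist_on >= duration)
    stop("stimulus_protocol: agonist_on outside [0, duration)")
  if (is.null(agonist_off)) agonist_off <- duration
  if (agonist_off <= agonist_on || agonist_off > duration)
    stop("stimulus_protocol: agonist_off must lie in (agonist_on, duration]")
  segs <- data.frame(t_start = c(0, agonist_on, agonist_off),
                     t_end = c(agonist_on, agonist_off, duration),
                     conc = c(0, conc, 0))
  segs <- segs[segs$t_end > segs$t_start, ]
  dt <- 1 / hz
  structure(list(duration = duration, hz = hz, dt = dt,
                 t = seq(0, duration, by = dt),
                 segments = segs, agonist_on = agonist_on,
                 agonist_off = if (agonist_off < duration) agonist_off else NA_real_,
                 conc = conc, exchange_tau = exchange_tau),
            class = "stimulus_protocol")
}

# Rate matrix A such that dx/dt = A x, for ligand concentration L,
# agonist-presence gate s and YM factor ymfac.
.rate_matrix <- function(network, L, s, ymfac) {
  ns <- length(network$species)
  A <- matrix(0, ns, ns, dimnames = list(network$species, network$species))
  for (tr in network$transitions) {
    g <- switch(tr$gate,
                ligand = L, on = s, off = 1 - s, exch = s * ymfac,
                always = 1)
    r <- tr$rate * g
    A[tr$to, tr$from] <- A[tr$to, tr$from] + r
    A[tr$from, tr$from] <- A[tr$from, tr$from] - r
  }
  A
}

.expm <- function(A) as.matrix(Matrix::expm(Matrix::Matrix(A)))

# YM factor at time t: 0 inside a blocking interval, 1 before any
# interval, `unblocked` only applies through the event split (the rate
# factor returns to 1 after washout; the retained blocked fraction is
# handled by .ym_events).
.ym_factor <- function(t, schedule) {
  if (is.null(schedule)) return(1)
  for (iv in schedule) if (t >= iv[1] && t < iv[2]) return(0)
  1
}

#' Integrate the reaction network over a stimulus protocol
#'
#' Deterministic mean-field integration of the linear (stimulus-gated)
#' rate equations. The propagator is a piecewise matrix exponential:
#' exact wherever the rate matrix is constant (which is everywhere except
#' the ~20 ms solution-exchange transients, where midpoint-evaluated
#' substeps are used). This makes the scheme immune to the stiffness of
#' the fast ligand-binding step. Occupancy is conserved to numerical
#' precision.
#'
#' At the end of each YM-254890 interval the blocked coupled complexes are
#' split: a fraction `ym_unblocked` of the accumulated `RLG` occupancy
#' proceeds normally, the remainder is moved to the absorbing `RLGb`
#' species (the mechanistic reading of the partial step-2 recovery seen
#' after YM washout).
#'
#' @param network A [build_network()] result.
#' @param protocol A [stimulus_protocol()].
#' @return An object of class `state_trajectory`: list with the time grid
#'   `$t` and the occupancy matrix `$occupancy` (one column per species,
#'   rows summing to 1).
#' @export
integrate_network <- function(network, protocol) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(protocol, "stimulus_protocol"))
  species <- network$species
  ns <- length(species)
  tgrid <- protocol$t
  nt <- length(tgrid)
  tau_ex <- protocol$exchange_tau
  segs <- protocol$segments

  # breakpoints where the target concentration or YM factor changes
  brk <- segs$t_start
  if (!is.null(network$ym_schedule))
    brk <- c(brk, unlist(network$ym_schedule))
  brk <- sort(unique(brk[brk > 0 & brk < protocol$duration]))
  ym_ends <- if (!is.null(network$ym_schedule))
    vapply(network$ym_schedule, `[`, numeric(1), 2) else numeric(0)

  conc_target <- function(t) {
    i <- findInterval(t, segs$t_start, left.open = FALSE)
    segs$conc[max(1L, min(i, nrow(segs)))]
  }
  # filtered concentration / presence: state carried along the sweep
  X <- matrix(NA_real_, nt, ns, dimnames = list(NULL, species))
  x <- numeric(ns); names(x) <- species
  x["R"] <- 1
  X[1, ] <- x

  L_cur <- conc_target(0)
  s_cur <- as.numeric(L_cur > 0)
  horizon <- if (tau_ex > 0) 14 * tau_ex else 0
  last_change <- 0        # time of the last breakpoint passed
  cacheA <- NULL; cacheP <- NULL; cache_dt <- NA_real_

  step_to <- function(t0, t1) {
    # advance x from t0 to t1 (no breakpoint strictly inside)
    h <- t1 - t0
    if (h <= 0) return(invisible())
    ct <- conc_target(t0)
    st <- as.numeric(ct > 0)
    ym <- .ym_factor(t0, network$ym_schedule)
    in_transient <- tau_ex > 0 && (t0 - last_change) < horizon
    if (!in_transient) {
      L_cur <<- ct; s_cur <<- st
      A <- .rate_matrix(network, ct, st, ym)
      if (is.null(cacheA) || !isTRUE(all.equal(cacheA, A)) ||
          !isTRUE(all.equal(cache_dt, h))) {
        cacheA <<- A; cache_dt <<- h; cacheP <<- .expm(A * h)
      }
      x <<- as.vector(cacheP %*% x)
    } else {
      nsub <- max(2L, ceiling(h / (tau_ex / 3)))
      hs <- h / nsub
      for (j in seq_len(nsub)) {
        tm <- t0 + (j - 0.5) * hs
        decay <- exp(-(tm - last_change) / tau_ex)
        Lm <- ct + (L_cur - ct) * decay
        sm <- st + (s_cur - st) * decay
        A <- .rate_matrix(network, Lm, sm, ym)
        x <<- as.vector(.expm(A * hs) %*% x)
      }
      # collapse the filter state at the end of the interval
      decay_end <- exp(-(t1 - last_change) / tau_ex)
      if (decay_end < 1e-8) { L_cur <<- ct; s_cur <<- st }
    }
    invisible()
  }

  i_rlg <- match("RLG", species)
  i_rlgb <- match("RLGb", species)
  apply_events <- function(tb) {
    if (length(ym_ends) && any(abs(ym_ends - tb) < 1e-12)) {
      f <- network$ym_unblocked
      x[i_rlgb] <<- x[i_rlgb] + (1 - f) * x[i_rlg]
      x[i_rlg] <<- f * x[i_rlg]
    }
  }

  for (i in 2:nt) {
    t0 <- tgrid[i - 1]; t1 <- tgrid[i]
    inside <- brk[brk > t0 + 1e-12 & brk <= t1 + 1e-12]
    for (tb in inside) {
      step_to(t0, tb)
      # record the pre-breakpoint filter state, then switch targets
      if (tau_ex > 0) {
        decay <- exp(-(tb - last_change) / tau_ex)
        ct_prev <- conc_target(tb - 1e-12)
        L_cur <- ct_prev + (L_cur - ct_prev) * decay
        s_cur <- as.numeric(ct_prev > 0) +
          (s_cur - as.numeric(ct_prev > 0)) * decay
      }
      apply_events(tb)
      last_change <- tb
      t0 <- tb
    }
    step_to(t0, t1)
    if (any(x < -1e-9))
      stop("integrate_network: negative occupancy at t = ", t1)
    x <- pmax(x, 0)
    tot <- sum(x)
    if (abs(tot - 1) > 1e-6)
      stop("integrate_network: occupancy not conserved at t = ", t1)
    x <- x / tot
    X[i, ] <- x
  }
  structure(list(t = tgrid, occupancy = X, protocol = protocol,
                 network = network),
            class = "state_trajectory")
}

#' @export
print.state_trajectory <- function(x, ...) {
  cat(sprintf("State trajectory: %d samples over %.1f s (%g Hz)\n",
              length(x$t), max(x$t), x$protocol$hz))
  cat("Final occupancy:\n")
  print(round(x$occupancy[nrow(x$occupancy), ], 4))
  invisible(x)
}

#' @export
plot.state_trajectory <- function(x, species = NULL, ...) {
  sp <- if (is.null(species)) colnames(x$occupancy) else species
  graphics::matplot(x$t, x$occupancy[, sp, drop = FALSE], type = "l",
                    lty = 1, xlab = "time (s)", ylab = "occupancy", ...)
  graphics::legend("right", legend = sp, col = seq_along(sp), lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
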