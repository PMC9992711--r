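#' Microscopic rate constants of the receptor-Gq cycle
#'
#' Container for the first-order rate constants of the lumped
#' activation/deactivation scheme. Each macroscopic kinetic phase of the
#' published traces maps onto one lumped rate:
#' \describe{
#'   \item{`k_couple`}{agonist-bound receptor + heterotrimeric Gq(GDP)
#'     association (pseudo-first-order; the G pool is non-depleting), the
#'     fast "step 1" of activation.}
#'   \item{`k_exch`}{lumped GDP release, GTP binding and Galpha/Gbetagamma
#'     separation on the receptor, the slow "step 2".}
#'   \item{`k_plc_on`, `k_plc_off`}{PLCbeta recruitment to / release from
#'     the receptor-bound Galpha-GTP.}
#'   \item{`k_bg_off`}{Gbetagamma (and intact trimer) release from the
#'     receptor after agonist washout, "step 1_OFF".}
#'   \item{`k_hyd`}{GTP hydrolysis and Galpha release, "step 2_OFF".}
#'   \item{`k_L_on`, `k_L_off`}{agonist binding/unbinding; fast relative to
#'     the 10 Hz sampling grid, with `k_L_off / k_L_on` the apparent
#'     dissociation constant in micromolar.}
#' }
#' Defaults are the reciprocal calibration of the wild-type intramolecular
#' sensor targets (see [macroscopic_targets()] and [calibrate_rates()]).
#'
#' @param k_couple,k_exch,k_plc_on,k_bg_off,k_plc_off,k_hyd First-order
#'   rates in 1/s, all >= 0.
#' @param k_L_on Agonist association rate in 1/(uM s).
#' @param k_L_off Agonist dissociation rate in 1/s.
#' @param jitter_cv Per-cell lognormal coefficient of variation applied to
#'   the rates by the synthetic-data generator.
#' @return An object of class `rate_set`.
#' @seealso [calibrate_rates()], [build_network()]
#' @export
rate_set <- function(k_couple = 1 / 0.22,
                     k_exch = 1 / 1.92,
                     k_plc_on = 0,
                     k_bg_off = 1 / 0.47,
                     k_plc_off = 1 / 5,
                     k_hyd = 1 / 20.02,
                     k_L_off = log(2) / 0.05,
                     k_L_on = (log(2) / 0.05) / 0.112,
                     jitter_cv = 0.2) {
  r <- list(k_couple = k_couple, k_exch = k_exch, k_plc_on = k_plc_on,
            k_bg_off = k_bg_off, k_plc_off = k_plc_off, k_hyd = k_hyd,
            k_L_on = k_L_on, k_L_off = k_L_off, jitter_cv = jitter_cv)
  num <- unlist(r)
  if (!all(is.finite(num)) || any(num < 0))
    stop("rate_set: all rates must be finite and non-negative")
  structure(r, class = "rate_set")
}

#' @export
print.rate_set <- function(x, ...) {
  cat("Receptor-Gq cycle rate set (1/s):\n")
  v <- unlist(x[c("k_couple", "k_exch", "k_plc_on", "k_bg_off",
                  "k_plc_off", "k_hyd", "k_L_off")])
  print(round(v, 4))
  cat(sprintf("k_L_on: %.3f 1/(uM s)  (apparent Kd %.4f uM), jitter CV %.2f\n",
              x$k_L_on, if (x$k_L_on > 0) x$k_L_off / x$k_L_on else NA_real_,
              x$jitter_cv))
  invisible(x)
}

#' Experimental condition of a simulated photometry recording
#'
#' Bundles the perturbation switches that modify the reaction network:
#' agonist identity and concentration, the intracellular guanine
#' nucleotide, an optional schedule of Gq-inhibitor (YM-254890) exposure,
#' the Galpha-q variant, the receptor variant, GRK2 co-expression and the
#' FRET construct observed.
#'
#' @param agonist `"OxoM"` or `"ACh"`.
#' @param concentration Agonist concentration in micromolar.
#' @param nucleotide `"GTP"`, `"GDPbetaS"` (non-exchangeable GDP analog,
#'   slows the exchange step) or `"GTPgammaS"` (non-hydrolyzable GTP
#'   analog, locks Galpha active and pre-separates the G pool).
#' @param ym_schedule Optional list of `c(t_start, t_end)` intervals (s)
#'   during which YM-254890 blocks GDP release; intervals must be
#'   non-overlapping.
#' @param galpha_variant `"WT"`, `"Q209L"` or `"R183C"`; the mutants are
#'   constitutively active (no GTPase activity, pre-separated at rest).
#' @param receptor_variant `"WT"`, `"TripleA"` or `"R166L"`; the mutants
#'   cannot couple to the G protein (`k_couple` forced to 0).
#' @param grk2 Logical; GRK2 co-expression (amplitude/noise scaling only).
#' @param construct Name of the FRET pair observed (see [fret_pairs()]).
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(agonist = c("OxoM", "ACh"),
                           concentration = 10,
                           nucleotide = c("GTP", "GDPbetaS", "GTPgammaS"),
                           ym_schedule = NULL,
                           galpha_variant = c("WT", "Q209L", "R183C"),
                           receptor_variant = c("WT", "TripleA", "R166L"),
                           grk2 = FALSE,
                           construct = "hM3R-YFP-CFP") {
  agonist <- match.arg(agonist)
  nucleotide <- match.arg(nucleotide)
  galpha_variant <- match.arg(galpha_variant)
  receptor_variant <- match.arg(receptor_variant)
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      !is.finite(concentration) || concentration < 0)
    stop("condition_spec: concentration must be a single non-negative number")
  if (!is.null(ym_schedule)) {
    if (!is.list(ym_schedule)) ym_schedule <- list(ym_schedule)
    iv <- do.call(rbind, ym_schedule)
    if (ncol(iv) != 2 || any(iv[, 2] <= iv[, 1]))
      stop("condition_spec: ym_schedule intervals must be c(start, end) with end > start")
    o <- order(iv[, 1])
    iv <- iv[o, , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] < iv[-nrow(iv), 2]))
      stop("condition_spec: ym_schedule intervals overlap")
    ym_schedule <- lapply(seq_len(nrow(iv)), function(i) iv[i, ])
  }
  structure(list(agonist = agonist, concentration = concentration,
                 nucleotide = nucleotide, ym_schedule = ym_schedule,
                 galpha_variant = galpha_variant,
                 receptor_variant = receptor_variant,
                 grk2 = grk2, construct = construct),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("Condition: %s %.3g uM, %s, Galpha %s, receptor %s, construct %s\n",
              x$agonist, x$concentration, x$nucleotide, x$galpha_variant,
              x$receptor_variant, x$construct))
  if (!is.null(x$ym_schedule))
    cat("YM-254890 intervals (s):",
        paste(vapply(x$ym_schedule, function(i) sprintf("[%g, %g]", i[1], i[2]),
                     ""), collapse = " "), "\n")
  invisible(x)
}

#' Macroscopic kinetic targets of the wild-type two-step response
#'
#' The printed time constants that the microscopic rates are calibrated
#' against: activation step 1 / step 2, deactivation step 1 / step 2, the
#' onset delay, and the fraction of the total amplitude carried by step 1.
#'
#' @param tau1_on,tau2_on,tau1_off,tau2_off Time constants in seconds.
#' @param delay_on Onset delay in seconds.
#' @param step1_fraction Fraction of total amplitude in step 1, in (0, 1).
#' @return An object of class `macroscopic_targets`.
#' @export
macroscopic_targets <- function(tau1_on = 0.22, tau2_on = 1.92,
                                tau1_off = 0.47, tau2_off = 20.02,
                                delay_on = 0.08, step1_fraction = 0.5) {
  v <- c(tau1_on = tau1_on, tau2_on = tau2_on, tau1_off = tau1_off,
         tau2_off = tau2_off, delay_on = delay_on)
  if (!all(is.finite(v)) || any(v <= 0))
    stop("macroscopic_targets: all times must be positive")
  if (step1_fraction <= 0 || step1_fraction >= 1)
    stop("macroscopic_targets: step1_fraction must lie in (0, 1)")
  structure(as.list(c(v, step1_fraction = step1_fraction)),
            class = "macroscopic_targets")
}

#' Calibrate microscopic rates to macroscopic time constants
#'
#' `"reciprocal"` mode sets each lumped rate to the inverse of its target
#' time constant (`k_couple = 1/tau1_on`, `k_exch = 1/tau2_on`,
#' `k_bg_off = 1/tau1_off`, `k_hyd = 1/tau2_off`). `"refined"` mode then
#' adjusts those four rates by derivative-free optimisation so that the
#' full noiseless simulate -> render -> ratio -> normalize -> windowed-fit
#' pipeline returns time constants matching the targets within `tol`
#' (relative).
#'
#' @param targets A [macroscopic_targets()] object.
#' @param mode `"reciprocal"` or `"refined"`.
#' @param base A `rate_set` supplying the rates not constrained by the
#'   targets (ligand kinetics, PLC rates, jitter).
#' @param tol Relative tolerance for refined mode (default 0.05).
#' @param maxit Maximum simplex iterations for refined mode.
#' @return A [rate_set()].
#' @export
calibrate_rates <- function(targets = macroscopic_targets(),
                            mode = c("reciprocal", "refined"),
                            base = rate_set(), tol = 0.05, maxit = 200) {
  mode <- match.arg(mode)
  stopifnot(inherits(targets, "macroscopic_targets"))
  recip <- rate_set(k_couple = 1 / targets$tau1_on,
                    k_exch = 1 / targets$tau2_on,
                    k_bg_off = 1 / targets$tau1_off,
                    k_hyd = 1 / targets$tau2_off,
                    k_plc_on = base$k_plc_on, k_plc_off = base$k_plc_off,
                    k_L_on = base$k_L_on, k_L_off = base$k_L_off,
                    jitter_cv = base$jitter_cv)
  if (mode == "reciprocal") return(recip)

  goal <- c(targets$tau1_on, targets$tau2_on, targets$tau1_off,
            targets$tau2_off)
  eval_taus <- function(logk) {
    k <- exp(logk)
    r <- recip
    r$k_couple <- k[1]; r$k_exch <- k[2]; r$k_bg_off <- k[3]; r$k_hyd <- k[4]
    .pipeline_taus(r)
  }
  obj <- function(logk) {
    taus <- tryCatch(eval_taus(logk), error = function(e) rep(NA_real_, 4))
    if (any(!is.finite(taus))) return(1e6)
    sum(((taus - goal) / goal)^2)
  }
  opt <- stats::optim(log(c(recip$k_couple, recip$k_exch, recip$k_bg_off,
                            recip$k_hyd)),
                      obj, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  taus <- eval_taus(opt$par)
  resid <- abs(taus - goal) / goal
  if (any(resid > tol))
    stop(sprintf(
      "calibrate_rates: refined mode did not converge; relative residuals %s",
      paste(sprintf("%.3f", resid), collapse = ", ")))
  k <- exp(opt$par)
  out <- recip
  out$k_couple <- k[1]; out$k_exch <- k[2]; out$k_bg_off <- k[3]
  out$k_hyd <- k[4]
  out
}

# Noiseless single-cell pipeline: returns c(tau1_on, tau2_on, tau1_off,
# tau2_off) for the intramolecular sensor under the given rates.
.pipeline_taus <- function(rates) {
  cond <- condition_spec()
  net <- build_network(cond, rates)
  proto <- stimulus_protocol(duration = 80, hz = 10, agonist_on = 10,
                             agonist_off = 45)
  traj <- integrate_network(net, proto)
  pair <- get_pair("hM3R-YFP-CFP")
  tr <- true_fretr(traj, pair)
  nt <- normalize_trace(tr, direction = pair$direction)
  f_on <- fit_two_step(nt, mode = "ON")
  f_off <- fit_two_step(nt, mode = "OFF")
  c(f_on$tau1, f_on$tau2, f_off$tau1, f_off$tau2)
}
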