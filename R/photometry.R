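#' True (noiseless) FRET ratio of a state trajectory
#'
#' Pointwise occupancy-weighted sum of the pair's coefficients,
#' \eqn{r(t) = \sum_s \epsilon_s x_s(t)}.
#'
#' @param traj A [integrate_network()] trajectory.
#' @param pair A [fret_pair_spec()].
#' @return A `fretr_trace`: list with `$t`, `$fretr` and the agonist marks.
#' @export
true_fretr <- function(traj, pair) {
  stopifnot(inherits(traj, "state_trajectory"),
            inherits(pair, "fret_pair_spec"))
  sp <- colnames(traj$occupancy)
  missing <- setdiff(sp, names(pair$epsilon))
  if (length(missing))
    stop("true_fretr: pair lacks coefficients for: ",
         paste(missing, collapse = ", "))
  r <- as.vector(traj$occupancy %*% pair$epsilon[sp])
  fretr_trace(traj$t, r, agonist_on = traj$protocol$agonist_on,
              agonist_off = traj$protocol$agonist_off)
}

#' Construct a FRET-ratio trace
#'
#' @param t Time grid in seconds.
#' @param fretr Ratio values (dimensionless, finite).
#' @param agonist_on,agonist_off Stimulus marks in seconds (`agonist_off`
#'   may be `NA` when the agonist stays on).
#' @return An object of class `fretr_trace`.
#' @export
fretr_trace <- function(t, fretr, agonist_on, agonist_off = NA_real_) {
  if (length(t) != length(fretr))
    stop("fretr_trace: t and fretr lengths differ")
  if (!all(is.finite(fretr)))
    stop("fretr_trace: non-finite ratio values")
  structure(list(t = t, fretr = fretr, agonist_on = agonist_on,
                 agonist_off = agonist_off),
            class = "fretr_trace")
}

#' @export
plot.fretr_trace <- function(x, ...) {
  graphics::plot(x$t, x$fretr, type = "l", xlab = "time (s)",
                 ylab = "FRETr", ...)
  graphics::abline(v = c(x$agonist_on, x$agonist_off), lty = 3)
  invisible(x)
}

#' Render two-channel photometry from a true ratio trace
#'
#' Generative inverse of the ratio formula: with donor level
#' \eqn{D(t) = D_0 e^{-\lambda t}},
#' \deqn{CFP_c(t) = D(t) + \eta_c, \quad
#'       YFP_c(t) = (r(t) + cFactor)\, D_a(t) + \eta_y,}
#' so that [compute_fretr()] exactly inverts the noiseless render when
#' both channels share one bleach rate (round-trip identity).
#'
#' @param trace A `fretr_trace` (the true ratio).
#' @param optics An [optics_spec()].
#' @param seed Optional integer; when given, the channel noise is drawn
#'   from a locally seeded RNG stream without disturbing the global one.
#' @return A `channel_traces` object: list with `$t`, `$CFPc`, `$YFPc`
#'   and the agonist marks.
#' @export
render_channels <- function(trace, optics, seed = NULL) {
  stopifnot(inherits(trace, "fretr_trace"), inherits(optics, "optics_spec"))
  n <- length(trace$t)
  if (!is.null(seed)) {
    runif(1)  # force RNG initialisation so the state can be restored
    old <- .Random.seed
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  don <- optics$donor_base * exp(-optics$bleach_rate * trace$t)
  acc <- optics$donor_base * exp(-optics$bleach_rate_acceptor * trace$t)
  cfp <- don
  yfp <- (trace$fretr + optics$cFactor) * acc
  if (optics$noise_sd_donor > 0)
    cfp <- cfp + stats::rnorm(n, 0, optics$noise_sd_donor)
  if (optics$noise_sd_acceptor > 0)
    yfp <- yfp + stats::rnorm(n, 0, optics$noise_sd_acceptor)
  if (optics$noise_sd_donor == 0 && any(cfp <= 0))
    stop("render_channels: non-positive donor signal in noiseless mode")
  structure(list(t = trace$t, CFPc = cfp, YFPc = yfp,
                 agonist_on = trace$agonist_on,
                 agonist_off = trace$agonist_off,
                 cFactor = optics$cFactor),
            class = "channel_traces")
}

# Per-cell lognormal multiplier with unit mean and coefficient of
# variation cv.
.lognorm_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic photometry dataset for a condition preset
#'
#' Simulates `n` cells under a named preset: per-cell lognormal jitter
#' (CV `jitter_cv`) on the kinetic rates and on the response amplitude,
#' deterministic integration of the jittered network, and channel
#' rendering with noise calibrated to the preset's published SNR. The
#' result is fully reproducible from `(preset, n, seed)`.
#'
#' @param preset Preset name (see [preset_names()]) or a preset list as
#'   returned by [get_preset()].
#' @param n Number of cells (>= 1).
#' @param seed Integer seed.
#' @param hz Optional sampling-rate override (Hz).
#' @param protocol Optional [stimulus_protocol()] override.
#' @param noise_scale Multiplier on the calibrated channel noise SD
#'   (0 disables noise).
#' @param jitter_cv Optional override of the preset's per-cell rate CV.
#' @return An object of class `cell_dataset`: list of per-cell channel
#'   traces plus ground-truth rates and metadata.
#' @export
generate_cells <- function(preset, n, seed, hz = NULL, protocol = NULL,
                           noise_scale = 1, jitter_cv = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  if (n < 1) stop("generate_cells: n must be >= 1")
  proto <- if (!is.null(protocol)) protocol else preset$protocol
  if (!is.null(hz)) {
    proto <- stimulus_protocol(duration = proto$duration, hz = hz,
                               agonist_on = proto$agonist_on,
                               agonist_off = if (is.na(proto$agonist_off))
                                 NULL else proto$agonist_off,
                               conc = proto$conc,
                               exchange_tau = proto$exchange_tau)
  }
  pair <- preset$pair
  rates <- preset$rates
  cv <- if (!is.null(jitter_cv)) jitter_cv else rates$jitter_cv
  optics0 <- preset$optics
  n_base <- max(2L, round(5 * proto$hz))
  amp <- abs(.pair_amplitude(pair))
  sd_ch <- if (!is.null(preset$snr) && noise_scale > 0 && amp > 0)
    noise_scale * noise_for_snr(preset$snr, amp, pair$baseline_fretr,
                                optics0, n_base) else 0

  runif(1)
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  jit_names <- c("k_couple", "k_exch", "k_bg_off", "k_hyd", "k_plc_on",
                 "k_plc_off")
  cells <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    r_i <- rates
    mult <- .lognorm_mult(length(jit_names), cv)
    for (j in seq_along(jit_names))
      r_i[[jit_names[j]]] <- rates[[jit_names[j]]] * mult[j]
    amp_mult <- .lognorm_mult(1, cv)
    eps_i <- pair$baseline_fretr +
      (pair$epsilon - pair$baseline_fretr) * amp_mult
    pair_i <- pair
    pair_i$epsilon <- eps_i
    net <- build_network(preset$condition, r_i,
                         gdpbs_factor = preset$gdpbs_factor,
                         ym_unblocked = preset$ym_unblocked)
    traj <- integrate_network(net, proto)
    tr <- true_fretr(traj, pair_i)
    optics_i <- optics0
    optics_i$noise_sd_donor <- sd_ch
    optics_i$noise_sd_acceptor <- sd_ch
    cells[[i]] <- render_channels(tr, optics_i)
    truth[[i]] <- list(cell_id = sprintf("cell_%03d", i),
                       rates = unclass(r_i)[jit_names],
                       amp_mult = amp_mult)
  }
  structure(list(cells = cells, ground_truth = truth,
                 preset = preset$name, condition = preset$condition,
                 pair = pair, optics = optics0, protocol = proto,
                 analysis = preset$analysis, n = n, seed = seed,
                 noise_sd = sd_ch),
            class = "cell_dataset")
}

# Activation amplitude of a pair: extreme active coefficient minus baseline.
.pair_amplitude <- function(pair) {
  span <- range(pair$epsilon)
  if (pair$direction == "decrease") span[1] - pair$baseline_fretr
  else span[2] - pair$baseline_fretr
}

#' @export
print.cell_dataset <- function(x, ...) {
  cat(sprintf("Synthetic photometry dataset: preset '%s', %d cells, seed %d\n",
              x$preset, x$n, x$seed))
  cat(sprintf("  %g Hz, %.0f s, channel noise SD %.3g a.u.\n",
              x$protocol$hz, x$protocol$duration, x$noise_sd))
  invisible(x)
}

#' Write / read a cell dataset as long-format CSV plus JSON ground truth
#'
#' The trace table has columns `cell_id`, `time_s`, `cfp_c`, `yfp_c`
#' (UTF-8, '.' decimal separator); the sidecar
#' `ground_truth.json` records the preset name, seed, protocol marks and
#' per-cell true rates.
#'
#' @param dataset A [generate_cells()] result.
#' @param dir Output directory (created if needed).
#' @return `write_cells` invisibly returns the two file paths;
#'   `read_cells` returns a list with the trace `data.frame` and the
#'   parsed ground truth.
#' @export
write_cells <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(dataset$cells), function(i) {
    ch <- dataset$cells[[i]]
    data.frame(cell_id = dataset$ground_truth[[i]]$cell_id,
               time_s = ch$t, cfp_c = ch$CFPc, yfp_c = ch$YFPc)
  })
  tab <- do.call(rbind, rows)
  csv <- file.path(dir, "traces.csv")
  utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  side <- list(preset = dataset$preset, seed = dataset$seed,
               n_cells = dataset$n, hz = dataset$protocol$hz,
               agonist_on = dataset$protocol$agonist_on,
               agonist_off = dataset$protocol$agonist_off,
               cFactor = dataset$optics$cFactor,
               noise_sd = dataset$noise_sd,
               cells = dataset$ground_truth)
  js <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(side, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(traces = csv, ground_truth = js))
}

#' @rdname write_cells
#' @export
read_cells <- function(dir) {
  csv <- file.path(dir, "traces.csv")
  js <- file.path(dir, "ground_truth.json")
  if (!file.exists(csv)) stop("read_cells: no traces.csv in ", dir)
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_s", "cfp_c", "yfp_c")
  if (!all(need %in% names(tab)))
    stop("read_cells: traces.csv must have columns ",
         paste(need, collapse = ", "))
  truth <- if (file.exists(js)) jsonlite::read_json(js) else NULL
  list(traces = tab, ground_truth = truth)
}
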