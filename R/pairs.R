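#' FRET pair specification
#'
#' Per-construct table of true FRET-ratio coefficients: the noiseless
#' FRET ratio of a cell is the occupancy-weighted sum
#' \eqn{\sum_s \epsilon_s x_s(t)} over network species. The six pairs of
#' the study are available pre-parameterised via [fret_pairs()] /
#' [get_pair()]; their coefficient values live in the preset registry
#' (`inst/extdata/presets.json`), not in code.
#'
#' @param name Construct name.
#' @param epsilon Named numeric vector: one finite coefficient per network
#'   species.
#' @param direction `"decrease"` or `"increase"`: the sign of the response
#'   upon activation. Must be consistent with the coefficients.
#' @param baseline_fretr Resting-state ratio; defaults to `epsilon["R"]`.
#' @return An object of class `fret_pair_spec`.
#' @export
fret_pair_spec <- function(name, epsilon, direction = c("decrease", "increase"),
                           baseline_fretr = unname(epsilon["R"])) {
  direction <- match.arg(direction)
  missing <- setdiff(.GQ_SPECIES, names(epsilon))
  if (length(missing))
    stop("fret_pair_spec: missing coefficients for species: ",
         paste(missing, collapse = ", "))
  if (!all(is.finite(epsilon)))
    stop("fret_pair_spec: coefficients must be finite")
  span <- range(epsilon[.GQ_SPECIES])
  act <- if (direction == "decrease") span[1] else span[2]
  if (sign(act - baseline_fretr) !=
      ifelse(direction == "decrease", -1, 1) && act != baseline_fretr)
    stop("fret_pair_spec: direction inconsistent with coefficients")
  structure(list(name = name, epsilon = epsilon[.GQ_SPECIES],
                 direction = direction, baseline_fretr = baseline_fretr),
            class = "fret_pair_spec")
}

#' @export
print.fret_pair_spec <- function(x, ...) {
  cat(sprintf("FRET pair %s (%s on activation), baseline FRETr %.3f\n",
              x$name, x$direction, x$baseline_fretr))
  print(round(x$epsilon, 3))
  invisible(x)
}

#' Registered FRET pairs
#'
#' @return Named list of all [fret_pair_spec()] objects in the preset
#'   registry.
#' @export
fret_pairs <- function() {
  reg <- .registry()
  lapply(reg$pairs, function(p)
    fret_pair_spec(p$name, unlist(p$epsilon), p$direction))
}

#' @rdname fret_pairs
#' @param name Construct name, e.g. `"hM3R-YFP-CFP"`.
#' @export
get_pair <- function(name) {
  reg <- .registry()
  p <- reg$pairs[[name]]
  if (is.null(p))
    stop("get_pair: unknown FRET pair '", name, "'")
  fret_pair_spec(p$name, unlist(p$epsilon), p$direction)
}

#' Optical model of the two-channel photometry rig
#'
#' @param cFactor Donor bleed-through ratio: fraction of CFP emission
#'   detected in the YFP channel (published calibration 0.45). The
#'   reverse bleed-through (0.02) is neglected, as in the original
#'   analysis.
#' @param donor_base Baseline donor intensity in arbitrary units.
#' @param noise_sd_donor,noise_sd_acceptor Additive i.i.d. Gaussian noise
#'   SD per sample and channel (a.u.).
#' @param bleach_rate Shared photobleaching rate (1/s); cancels in the
#'   ratio.
#' @param bleach_rate_acceptor Optional separate acceptor bleach rate for
#'   the non-cancelling differential mode (default: equal to
#'   `bleach_rate`).
#' @return An object of class `optics_spec`.
#' @export
optics_spec <- function(cFactor = 0.45, donor_base = 100,
                        noise_sd_donor = 0, noise_sd_acceptor = 0,
                        bleach_rate = 0, bleach_rate_acceptor = NULL) {
  v <- c(cFactor, donor_base, noise_sd_donor, noise_sd_acceptor, bleach_rate)
  if (!all(is.finite(v)) || any(v < 0) || donor_base <= 0)
    stop("optics_spec: all parameters must be non-negative (donor_base > 0)")
  if (is.null(bleach_rate_acceptor)) bleach_rate_acceptor <- bleach_rate
  structure(list(cFactor = cFactor, donor_base = donor_base,
                 noise_sd_donor = noise_sd_donor,
                 noise_sd_acceptor = noise_sd_acceptor,
                 bleach_rate = bleach_rate,
                 bleach_rate_acceptor = bleach_rate_acceptor),
            class = "optics_spec")
}

#' Channel noise SD needed to hit a target pipeline SNR
#'
#' The pipeline SNR is the maximum response amplitude divided by the
#' standard error of the baseline ratio (SD over the 5-s baseline window
#' divided by sqrt of its sample count). For equal per-channel noise SD
#' \eqn{\sigma} the first-order ratio noise is
#' \eqn{\sigma_r = (\sigma / D)\sqrt{1 + (r_0 + c)^2}} with donor level
#' \eqn{D}, baseline ratio \eqn{r_0} and bleed-through \eqn{c}; inverting
#' gives the per-channel SD that calibrates the renderer to the published
#' SNR values.
#'
#' @param target_snr Desired pipeline SNR.
#' @param amplitude Response amplitude in FRET-ratio units.
#' @param baseline_ratio Resting FRET ratio.
#' @param optics An [optics_spec()] (for `cFactor` and `donor_base`).
#' @param n_baseline Number of baseline samples (5 s window x sampling
#'   rate).
#' @return Per-channel noise SD in a.u.
#' @export
noise_for_snr <- function(target_snr, amplitude, baseline_ratio, optics,
                          n_baseline = 50) {
  stopifnot(target_snr > 0, amplitude > 0, n_baseline >= 2)
  sigma_r <- amplitude * sqrt(n_baseline) / target_snr
  sigma_r * optics$donor_base /
    sqrt(1 + (baseline_ratio + optics$cFactor)^2)
}
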