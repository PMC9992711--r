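#' Receptor-Gq cycle model object
#'
#' Convenience front door tying a condition, a rate set, a FRET pair and
#' a protocol into one model object with the usual methods: `print`,
#' `coef` (the rates), `predict` (the noiseless ratio trace) and
#' `simulate` (noisy multi-cell datasets).
#'
#' @param condition A [condition_spec()].
#' @param rates A [rate_set()].
#' @param pair A [fret_pair_spec()] or pair name.
#' @param protocol A [stimulus_protocol()].
#' @param optics An [optics_spec()].
#' @param snr Target pipeline SNR used when simulating with noise
#'   (`NULL` = noiseless).
#' @return An object of class `gq_model`.
#' @examples
#' m <- gq_model()
#' head(predict(m)$fretr)
#' @export
gq_model <- function(condition = condition_spec(), rates = rate_set(),
                     pair = "hM3R-YFP-CFP",
                     protocol = stimulus_protocol(80, hz = 10,
                                                  agonist_on = 10,
                                                  agonist_off = 45),
                     optics = optics_spec(), snr = NULL) {
  if (is.character(pair)) pair <- get_pair(pair)
  structure(list(condition = condition, rates = rates, pair = pair,
                 protocol = protocol, optics = optics, snr = snr),
            class = "gq_model")
}

#' @export
print.gq_model <- function(x, ...) {
  cat("Receptor-Gq cycle model\n")
  print(x$condition)
  print(x$rates)
  cat(sprintf("Pair %s; protocol %.0f s at %g Hz\n", x$pair$name,
              x$protocol$duration, x$protocol$hz))
  invisible(x)
}

#' @export
coef.gq_model <- function(object, ...) {
  unlist(unclass(object$rates)[c("k_couple", "k_exch", "k_plc_on",
                                 "k_bg_off", "k_plc_off", "k_hyd",
                                 "k_L_on", "k_L_off")])
}

#' @export
predict.gq_model <- function(object, ...) {
  net <- build_network(object$condition, object$rates)
  traj <- integrate_network(net, object$protocol)
  true_fretr(traj, object$pair)
}

#' @export
simulate.gq_model <- function(object, nsim = 1, seed = 1, ...) {
  preset <- structure(list(
    name = "ad_hoc_model", condition = object$condition,
    rates = object$rates, pair = object$pair, optics = object$optics,
    protocol = object$protocol, snr = object$snr,
    analysis = list(mode = "single_step"),
    gdpbs_factor = 0.2, ym_unblocked = 0.31), class = "gq_preset")
  generate_cells(preset, n = nsim, seed = seed)
}
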