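# Registry cache environment
.gqfret_env <- new.env(parent = emptyenv())

.registry <- function() {
  if (is.null(.gqfret_env$registry)) {
    path <- system.file("extdata", "presets.json", package = "gqfret")
    if (path == "")
      path <- file.path("inst", "extdata", "presets.json")  # load_all fallback
    .gqfret_env$registry <- jsonlite::read_json(path)
  }
  .gqfret_env$registry
}

#' Names of the registered condition presets
#'
#' One entry per experimental condition of the study: the wild-type
#' intramolecular sensor under GTP / GDP-beta-S / GTP-gamma-S, the
#' constitutively active Galpha mutants, the coupling-dead receptor
#' mutants, the YM-254890 hold and washout schedules, the intermolecular
#' pair constructs, the PLCbeta pairs, and binding-only dose-response
#' presets.
#'
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.registry()$presets)

#' Retrieve a fully resolved condition preset
#'
#' Resolves a registry entry into executable objects: a
#' [condition_spec()], a [rate_set()] (reciprocal of the preset's
#' macroscopic time constants), the [fret_pair_spec()], an
#' [optics_spec()], and the default [stimulus_protocol()], plus the
#' preset's target SNR and analysis mode.
#'
#' @param name Preset name (see [preset_names()]).
#' @return A list of class `gq_preset`.
#' @export
get_preset <- function(name) {
  reg <- .registry()
  p <- reg$presets[[name]]
  if (is.null(p))
    stop("get_preset: unknown preset '", name, "'; see preset_names()")
  d <- reg$defaults
  cn <- p$condition
  ym <- if (!is.null(cn$ym_schedule))
    lapply(cn$ym_schedule, function(iv) c(iv[[1]], iv[[2]])) else NULL
  condition <- condition_spec(
    agonist = cn$agonist, concentration = cn$concentration,
    nucleotide = cn$nucleotide, ym_schedule = ym,
    galpha_variant = cn$galpha_variant,
    receptor_variant = cn$receptor_variant,
    grk2 = isTRUE(cn$grk2),
    construct = if (!is.null(cn$construct)) cn$construct else "hM3R-YFP-CFP")
  r <- p$rates
  kLoff <- d$k_L_off
  rates <- rate_set(
    k_couple = 1 / r$k_couple_tau,
    k_exch = 1 / r$k_exch_tau,
    k_bg_off = 1 / r$k_bg_off_tau,
    k_hyd = 1 / r$k_hyd_tau,
    k_plc_on = if (!is.null(r$k_plc_on_tau)) 1 / r$k_plc_on_tau else 0,
    k_plc_off = if (!is.null(r$k_plc_off_tau)) 1 / r$k_plc_off_tau else 1 / 5,
    k_L_off = kLoff,
    k_L_on = kLoff / r$kd_um,
    jitter_cv = d$jitter_cv)
  pr <- p$protocol
  protocol <- stimulus_protocol(
    duration = pr$duration, hz = pr$hz, agonist_on = pr$agonist_on,
    agonist_off = pr$agonist_off, conc = pr$conc,
    exchange_tau = d$exchange_tau)
  optics <- optics_spec(cFactor = d$optics$cFactor,
                        donor_base = d$optics$donor_base,
                        bleach_rate = d$optics$bleach_rate)
  structure(list(
    name = name, condition = condition, rates = rates,
    pair = get_pair(p$pair), optics = optics, protocol = protocol,
    snr = p$snr,
    analysis = list(mode = p$analysis$mode),
    gdpbs_factor = if (!is.null(p$gdpbs_factor)) p$gdpbs_factor
                   else d$gdpbs_factor,
    ym_unblocked = if (!is.null(p$ym_unblocked)) p$ym_unblocked
                   else d$ym_unblocked),
    class = "gq_preset")
}

#' @export
print.gq_preset <- function(x, ...) {
  cat("Preset '", x$name, "'\n", sep = "")
  print(x$condition)
  cat(sprintf("  pair %s, target SNR %s, analysis mode %s\n",
              x$pair$name, format(x$snr), x$analysis$mode))
  invisible(x)
}
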