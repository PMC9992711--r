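#' Signal-to-noise ratio of a FRET-ratio trace
#'
#' Maximum response amplitude divided by the standard error of the
#' baseline: \eqn{SNR = \max_t |\Delta FRETr(t)| / SE_{baseline}}, with
#' the amplitude measured relative to the mean of the 5-s pre-agonist
#' window. `"sem"` mode (the default, the literal reading of "standard
#' error") divides the baseline SD by the square root of the baseline
#' sample count; `"sd"` mode uses the raw SD.
#'
#' @param trace A `fretr_trace` (or a `normalized_trace`).
#' @param baseline_window Baseline length in seconds.
#' @param se_mode `"sem"` or `"sd"`.
#' @return A list with `snr`, `amplitude`, `baseline_se`, `n_baseline`.
#'   Zero baseline variability yields `snr = Inf` with a flag.
#' @export
compute_snr <- function(trace, baseline_window = 5,
                        se_mode = c("sem", "sd")) {
  se_mode <- match.arg(se_mode)
  t <- trace$t
  y <- if (!is.null(trace$value)) trace$value else trace$fretr
  on <- trace$agonist_on
  wb <- t >= on - baseline_window & t < on
  if (sum(wb) < 2) stop("compute_snr: baseline window missing")
  base <- y[wb]
  se <- stats::sd(base)
  if (se_mode == "sem") se <- se / sqrt(length(base))
  amp <- max(abs(y[t >= on] - mean(base)))
  list(snr = if (se > 0) amp / se else Inf,
       amplitude = amp, baseline_se = se, n_baseline = length(base),
       degenerate = se == 0, se_mode = se_mode)
}

#' Percent step distributions
#'
#' Implements the published percentage formulas.
#' \describe{
#'   \item{`two_step_on` / `two_step_off`}{per-step fitted amplitude as a
#'     percentage of the maximum activation amplitude,
#'     \eqn{100 \times A_{step} / \Delta FRETr_{max}}; the OFF variant is
#'     referenced to the activation maximum too. Any unexplained
#'     remainder of the total is reported.}
#'   \item{`single_step_on`}{per-cell mean normalized amplitude over the
#'     2.5-s window before washout, divided by the same quantity of the
#'     supplied group-average trace (both measured against the initial
#'     value 1).}
#'   \item{`single_step_off`}{fitted deactivation amplitude as a
#'     percentage of the maximum activation amplitude.}
#' }
#'
#' @param fit A `fret_fit` (for the fit-based kinds). For
#'   `single_step_on`, a `normalized_trace` for the individual cell.
#' @param kind One of `"two_step_on"`, `"two_step_off"`,
#'   `"single_step_on"`, `"single_step_off"`.
#' @param max_amp Maximum activation amplitude. The published analysis
#'   takes this from the least-squares fit, so for a two-step fit it
#'   defaults to the summed fitted step amplitudes; for the OFF variants
#'   pass the activation fit's total explicitly.
#' @param group_trace Group-average `normalized_trace`, required for
#'   `single_step_on`.
#' @param pre_wash_window Averaging window (s) for the single-step ON
#'   variant.
#' @return Named list of percentages (plus `remainder` for the two-step
#'   kinds).
#' @export
percent_metrics <- function(fit, kind = c("two_step_on", "two_step_off",
                                          "single_step_on",
                                          "single_step_off"),
                            max_amp = NULL, group_trace = NULL,
                            pre_wash_window = 2.5) {
  kind <- match.arg(kind)
  if (kind == "single_step_on") {
    trace <- if (inherits(fit, "fret_fit")) fit$trace else fit
    if (is.null(group_trace))
      stop("percent_metrics: single_step_on requires the group-average trace")
    cell <- .prewash_amp(trace, pre_wash_window)
    grp <- .prewash_amp(group_trace, pre_wash_window)
    if (grp == 0) stop("percent_metrics: zero group-average amplitude")
    return(list(pct_on = 100 * cell / grp))
  }
  stopifnot(inherits(fit, "fret_fit"))
  if (is.null(max_amp)) {
    max_amp <- if (fit$kind == "two_step") fit$amp1 + fit$amp2
               else .max_activation_amp(fit$trace)
  }
  if (max_amp <= 0)
    stop("percent_metrics: zero maximum activation amplitude")
  if (kind == "single_step_off") {
    if (fit$mode != "OFF") stop("percent_metrics: OFF-mode fit required")
    return(list(pct_off = 100 * fit$amp1 / max_amp))
  }
  if (fit$kind != "two_step")
    stop("percent_metrics: two-step fit required for kind ", kind)
  p1 <- 100 * fit$amp1 / max_amp
  p2 <- 100 * fit$amp2 / max_amp
  if (p1 + p2 > 100) {  # normalize overshoot from fit extrapolation
    s <- 100 / (p1 + p2)
    p1 <- p1 * s; p2 <- p2 * s
  }
  out <- list(pct_step1 = p1, pct_step2 = p2,
              remainder = max(0, 100 - p1 - p2))
  names(out)[1:2] <- if (kind == "two_step_on")
    c("pct_step1_on", "pct_step2_on") else c("pct_step1_off", "pct_step2_off")
  out
}

# Mean |deviation from 1| over the pre-washout window of a normalized trace
.prewash_amp <- function(trace, window = 2.5) {
  off <- trace$agonist_off
  if (is.null(off) || is.na(off)) off <- max(trace$t)
  sel <- trace$t >= off - window & trace$t < off
  abs(mean(trace$value[sel]) - 1)
}

# Maximum activation amplitude of a normalized trace (|value - 1| while
# the agonist is on)
.max_activation_amp <- function(trace) {
  off <- trace$agonist_off
  if (is.null(off) || is.na(off)) off <- max(trace$t)
  sel <- trace$t >= trace$agonist_on & trace$t <= off
  max(abs(trace$value[sel] - 1))
}

#' Mean +/- SEM summary of per-cell fit metrics
#'
#' @param fits List of `fret_fit` objects (one per cell); entries that
#'   are `NULL` or errors are skipped.
#' @param condition Condition label for the summary rows.
#' @param extra Optional named list of additional per-cell numeric
#'   vectors to summarize (e.g. SNR or percentages).
#' @return A `data.frame` with columns `condition`, `metric`, `mean`,
#'   `sem`, `n`. SEM is `sd/sqrt(n)`; it is `NA` for `n = 1`.
#' @export
summarize_fits <- function(fits, condition = "", extra = list()) {
  fits <- Filter(function(f) inherits(f, "fret_fit"), fits)
  metrics <- list()
  grab <- function(name, vals) {
    vals <- vals[is.finite(vals)]
    if (length(vals)) metrics[[name]] <<- vals
  }
  if (length(fits)) {
    grab("delay", vapply(fits, `[[`, numeric(1), "delay"))
    grab("tau1", vapply(fits, `[[`, numeric(1), "tau1"))
    grab("amp1", vapply(fits, `[[`, numeric(1), "amp1"))
    grab("tau2", vapply(fits, `[[`, numeric(1), "tau2"))
    grab("amp2", vapply(fits, `[[`, numeric(1), "amp2"))
  }
  for (nm in names(extra)) grab(nm, extra[[nm]])
  rows <- lapply(names(metrics), function(nm) {
    v <- metrics[[nm]]
    data.frame(condition = condition, metric = nm, mean = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                     else NA_real_,
               n = length(v))
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
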