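#' Bleed-through-corrected FRET ratio from two-channel photometry
#'
#' \deqn{FRETr = (YFP_c - cFactor \times CFP_c) / CFP_c}
#' where `YFPc` is the acceptor-channel signal under donor excitation and
#' `CFPc` the donor channel. `cFactor` is the donor bleed-through ratio
#' (published calibration 0.45); the acceptor-into-donor bleed-through is
#' neglected.
#'
#' @param channels A `channel_traces` object (see [render_channels()]), or
#'   any list with `$t`, `$CFPc`, `$YFPc` and agonist marks.
#' @param cFactor Bleed-through ratio; defaults to the value stored with
#'   the channels, else 0.45.
#' @return A `fretr_trace`.
#' @export
compute_fretr <- function(channels, cFactor = NULL) {
  if (is.null(cFactor))
    cFactor <- if (!is.null(channels$cFactor)) channels$cFactor else 0.45
  bad <- which(channels$CFPc <= 0)
  if (length(bad))
    stop("compute_fretr: non-positive donor sample at index ", bad[1])
  r <- (channels$YFPc - cFactor * channels$CFPc) / channels$CFPc
  fretr_trace(channels$t, r, agonist_on = channels$agonist_on,
              agonist_off = channels$agonist_off)
}

#' Affine normalization of a FRET-ratio trace
#'
#' The mean ratio over the 5-s window before agonist application is pinned
#' to 1; the mean over the 5-s window before washout is pinned to 0 for
#' decreasing responses or 2 for increasing ones. The map is affine, so
#' normalizing an already-normalized trace is the identity.
#'
#' @param trace A `fretr_trace` with valid agonist marks.
#' @param direction `"decrease"` or `"increase"`.
#' @param baseline_window,plateau_window Window lengths in seconds.
#' @return A `normalized_trace`: list with `$t`, `$value`, `$direction`
#'   and the marks.
#' @export
normalize_trace <- function(trace, direction = c("decrease", "increase"),
                            baseline_window = 5, plateau_window = 5) {
  direction <- match.arg(direction)
  t <- trace$t
  on <- trace$agonist_on
  off <- trace$agonist_off
  if (is.null(off) || is.na(off)) off <- max(t)
  if (on - min(t) < baseline_window - 1e-9)
    stop("normalize_trace: fewer than ", baseline_window,
         " s of pre-agonist baseline")
  wb <- t >= on - baseline_window & t < on
  wp <- t >= off - plateau_window & t < off
  if (sum(wp) < 2)
    stop("normalize_trace: fewer than ", plateau_window,
         " s of pre-washout data")
  y <- if (!is.null(trace$value)) trace$value else trace$fretr
  mb <- mean(y[wb]); mp <- mean(y[wp])
  if (abs(mb - mp) < 1e-12 * max(1, abs(mb)))
    stop("normalize_trace: degenerate trace (baseline and plateau means equal)")
  v <- if (direction == "decrease") (y - mp) / (mb - mp)
       else 1 + (y - mb) / (mp - mb)
  structure(list(t = t, value = v, direction = direction,
                 agonist_on = on,
                 agonist_off = if (identical(off, max(t))) NA_real_ else off,
                 baseline_window = baseline_window,
                 plateau_window = plateau_window),
            class = "normalized_trace")
}

#' @export
plot.normalized_trace <- function(x, ...) {
  graphics::plot(x$t, x$value, type = "l", xlab = "time (s)",
                 ylab = "normalized FRETr", ...)
  graphics::abline(v = c(x$agonist_on, x$agonist_off), lty = 3)
  invisible(x)
}
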