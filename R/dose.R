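#' Hill (four-parameter logistic) dose-response fit
#'
#' Least-squares fit of
#' \deqn{y(c) = bottom + (top - bottom) \frac{c^h}{c^h + EC_{50}^h}}
#' to normalized responses. On normalized responses the bottom is fixed
#' to 0 unless `free_bottom = TRUE`. By construction the response at
#' `c = EC50` is halfway between bottom and top.
#'
#' @param conc Concentrations in micromolar (>= 4 values recommended,
#'   spanning the transition).
#' @param resp Responses (same length).
#' @param free_bottom Free the lower asymptote.
#' @return A `dose_fit` object with `ec50` (uM), `hill`, `top`, `bottom`,
#'   and a flag `extrapolated` when the data do not bracket the fitted
#'   EC50.
#' @export
fit_dose_response <- function(conc, resp, free_bottom = FALSE) {
  stopifnot(length(conc) == length(resp), length(conc) >= 4,
            all(conc > 0), all(is.finite(resp)))
  o <- order(conc)
  conc <- conc[o]; resp <- resp[o]
  top0 <- max(resp)
  ec0 <- stats::approx(resp, conc, xout = (max(resp) + min(resp)) / 2,
                       ties = "ordered")$y
  if (!is.finite(ec0)) ec0 <- exp(mean(log(range(conc))))
  dat <- data.frame(conc = conc, resp = resp)
  fits <- list()
  for (h0 in c(0.7, 1, 1.5)) {
    f <- tryCatch(suppressWarnings({
      if (free_bottom)
        stats::nls(resp ~ bottom + (top - bottom) * conc^h /
                     (conc^h + ec50^h),
                   data = dat,
                   start = list(bottom = min(resp), top = top0, ec50 = ec0,
                                h = h0),
                   algorithm = "port",
                   lower = c(-Inf, -Inf, min(conc) / 1e3, 0.1),
                   upper = c(Inf, Inf, max(conc) * 1e3, 10),
                   control = stats::nls.control(warnOnly = TRUE))
      else
        stats::nls(resp ~ top * conc^h / (conc^h + ec50^h), data = dat,
                   start = list(top = top0, ec50 = ec0, h = h0),
                   algorithm = "port",
                   lower = c(-Inf, min(conc) / 1e3, 0.1),
                   upper = c(Inf, max(conc) * 1e3, 10),
                   control = stats::nls.control(warnOnly = TRUE))
    }), error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("fit_dose_response: no converging fit")
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  f <- fits[[which.min(rss)]]
  cf <- stats::coef(f)
  ec50 <- unname(cf["ec50"])
  structure(list(ec50 = ec50, hill = unname(cf["h"]),
                 top = unname(cf["top"]),
                 bottom = if (free_bottom) unname(cf["bottom"]) else 0,
                 extrapolated = ec50 < min(conc) || ec50 > max(conc),
                 conc = conc, resp = resp, rss = min(rss)),
            class = "dose_fit")
}

#' @export
print.dose_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 = %.4g uM, hill = %.2f, top = %.3g, bottom = %.3g%s\n",
              x$ec50, x$hill, x$top, x$bottom,
              if (x$extrapolated) " [extrapolated]" else ""))
  invisible(x)
}

#' @export
coef.dose_fit <- function(object, ...)
  c(ec50 = object$ec50, hill = object$hill, top = object$top,
    bottom = object$bottom)

#' @export
predict.dose_fit <- function(object, conc = NULL, ...) {
  if (is.null(conc)) conc <- object$conc
  object$bottom + (object$top - object$bottom) * conc^object$hill /
    (conc^object$hill + object$ec50^object$hill)
}

#' @export
plot.dose_fit <- function(x, ...) {
  graphics::plot(x$conc, x$resp, log = "x", xlab = "concentration (uM)",
                 ylab = "response", ...)
  cc <- exp(seq(log(min(x$conc)), log(max(x$conc)), length.out = 100))
  graphics::lines(cc, predict(x, cc), col = 2)
  invisible(x)
}

#' Sigmoid half-time (T50) of an activation curve
#'
#' Logistic least-squares fit
#' \eqn{y(t) = c_0 + A / (1 + e^{-(t - T_{50})/k})}; `T50` is the
#' midpoint time. Used for the half-time of confocal relative-intensity
#' activation curves. A time-shifted input shifts `T50` by the same
#' amount.
#'
#' @param t Time (s).
#' @param y Relative intensity (monotone trend).
#' @param resid_threshold Flag the fit when the residual SD exceeds this
#'   fraction of the fitted amplitude (non-sigmoid input).
#' @return List with `t50` (s), `slope`, `amplitude`, `offset`,
#'   `flagged`.
#' @export
fit_t50 <- function(t, y, resid_threshold = 0.15) {
  stopifnot(length(t) == length(y), length(t) >= 5)
  a0 <- diff(range(y))
  t0 <- stats::approx(y, t, xout = mean(range(y)), ties = "ordered")$y
  if (!is.finite(t0)) t0 <- mean(range(t))
  span <- diff(range(t))
  fits <- list()
  for (k0 in span / c(30, 10, 4)) {
    f <- tryCatch(suppressWarnings(
      stats::nls(y ~ c0 + A / (1 + exp(-(t - t50) / k)),
                 data = data.frame(t = t, y = y),
                 start = list(c0 = min(y), A = a0, t50 = t0, k = k0),
                 algorithm = "port",
                 lower = c(-Inf, -Inf, min(t) - span, 1e-3),
                 upper = c(Inf, Inf, max(t) + span, span),
                 control = stats::nls.control(warnOnly = TRUE))),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (!length(fits)) stop("fit_t50: no converging logistic fit")
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  f <- fits[[which.min(rss)]]
  cf <- stats::coef(f)
  rs <- sqrt(min(rss) / length(t))
  structure(list(t50 = unname(cf["t50"]), slope = unname(cf["k"]),
                 amplitude = unname(cf["A"]), offset = unname(cf["c0"]),
                 flagged = rs > resid_threshold * abs(cf["A"])),
            class = "t50_fit")
}

#' @export
print.t50_fit <- function(x, ...) {
  cat(sprintf("Sigmoid fit: T50 = %.2f s (slope %.2f s, amplitude %.3g)%s\n",
              x$t50, x$slope, x$amplitude,
              if (x$flagged) " [non-sigmoid residuals]" else ""))
  invisible(x)
}

#' Synthetic concentration-response series from a binding-occupancy preset
#'
#' Simulates `n_cells` cells at each concentration of a log-spaced dose
#' series from a binding-only occupancy preset, measures the mean
#' normalized response over the 2.5-s window before washout (against the
#' initial value 1), and Hill-fits the per-concentration means.
#'
#' @param preset Preset name (default the Oxo-M occupancy preset).
#' @param conc Concentrations in micromolar.
#' @param n_cells Cells per concentration.
#' @param seed Integer seed (each concentration uses an offset stream).
#' @return List with the per-concentration mean responses (`series`) and
#'   the [fit_dose_response()] result (`fit`).
#' @export
dose_response_series <- function(preset = "oxom_dose",
                                 conc = 10^seq(-2.5, 0.5, by = 0.5),
                                 n_cells = 10, seed = 1) {
  p <- get_preset(preset)
  resp <- numeric(length(conc))
  for (i in seq_along(conc)) {
    proto <- stimulus_protocol(duration = p$protocol$duration,
                               hz = p$protocol$hz,
                               agonist_on = p$protocol$agonist_on,
                               agonist_off = p$protocol$agonist_off,
                               conc = conc[i],
                               exchange_tau = p$protocol$exchange_tau)
    ds <- generate_cells(p, n_cells, seed = seed + 1000L * i,
                         protocol = proto)
    amps <- vapply(ds$cells, function(ch) {
      tr <- compute_fretr(ch)
      # relative trace: divide by the 5-s pre-agonist baseline mean
      base <- mean(tr$fretr[tr$t >= tr$agonist_on - 5 & tr$t < tr$agonist_on])
      rel <- tr$fretr / base
      off <- tr$agonist_off
      sel <- tr$t >= off - 2.5 & tr$t < off
      abs(mean(rel[sel]) - 1)
    }, numeric(1))
    resp[i] <- mean(amps)
  }
  fit <- fit_dose_response(conc, resp)
  list(series = data.frame(conc = conc, response = resp), fit = fit)
}
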