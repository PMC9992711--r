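#' Analyze a synthetic photometry dataset with the standard pipeline
#'
#' Per cell: bleed-through-corrected ratio, SNR, affine normalization,
#' then the preset's fit mode (windowed two-step decomposition or
#' single-step fit with delay), ON and -- when the protocol includes a
#' washout -- OFF. A failing cell is isolated: its error is recorded and
#' the remaining cells are processed.
#'
#' @param dataset A [generate_cells()] result.
#' @param mode Fit mode override (`"two_step"` or `"single_step"`);
#'   defaults to the preset's analysis mode.
#' @return A list of class `preset_analysis`: per-cell results
#'   (`$cells`), the per-condition summary table (`$summary`), and the
#'   failure count.
#' @export
analyze_cells <- function(dataset, mode = NULL) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (is.null(mode)) mode <- dataset$analysis$mode
  direction <- dataset$pair$direction
  has_off <- !is.na(dataset$protocol$agonist_off) &&
    (dataset$protocol$duration - dataset$protocol$agonist_off) >= 10
  res <- vector("list", length(dataset$cells))
  failures <- character(0)
  for (i in seq_along(dataset$cells)) {
    res[[i]] <- tryCatch({
      ch <- dataset$cells[[i]]
      tr <- compute_fretr(ch)
      snr <- compute_snr(tr)
      nt <- normalize_trace(tr, direction = direction)
      if (mode == "two_step") {
        f_on <- fit_two_step(nt, mode = "ON")
        pct <- percent_metrics(f_on, "two_step_on")
        f_off <- if (has_off) fit_two_step(nt, mode = "OFF") else NULL
      } else {
        f_on <- fit_single_step(nt, mode = "ON")
        pct <- NULL
        f_off <- if (has_off) fit_single_step(nt, mode = "OFF") else NULL
      }
      list(fretr = tr, normalized = nt, snr = snr, fit_on = f_on,
           fit_off = f_off, pct = pct)
    }, error = function(e) {
      failures <<- c(failures, sprintf("cell %d: %s", i, conditionMessage(e)))
      NULL
    })
  }
  ok <- Filter(Negate(is.null), res)
  metrics <- list(
    delay_on = vapply(ok, function(r) r$fit_on$delay, numeric(1)),
    tau1_on = vapply(ok, function(r) r$fit_on$tau1, numeric(1)),
    amp1_on = vapply(ok, function(r) r$fit_on$amp1, numeric(1)),
    snr = vapply(ok, function(r) r$snr$snr, numeric(1)))
  if (mode == "two_step") {
    metrics$tau2_on <- vapply(ok, function(r) r$fit_on$tau2, numeric(1))
    metrics$amp2_on <- vapply(ok, function(r) r$fit_on$amp2, numeric(1))
    metrics$pct_step1_on <-
      vapply(ok, function(r) r$pct$pct_step1_on, numeric(1))
    metrics$pct_step2_on <-
      vapply(ok, function(r) r$pct$pct_step2_on, numeric(1))
  }
  if (has_off) {
    metrics$tau1_off <- vapply(ok, function(r) r$fit_off$tau1, numeric(1))
    if (mode == "two_step")
      metrics$tau2_off <- vapply(ok, function(r) r$fit_off$tau2, numeric(1))
  }
  summary <- summarize_fits(list(), condition = dataset$preset,
                            extra = metrics)
  structure(list(cells = res, summary = summary, metrics = metrics,
                 preset = dataset$preset, mode = mode,
                 n_failed = length(failures), failures = failures),
            class = "preset_analysis")
}

#' @export
print.preset_analysis <- function(x, ...) {
  cat(sprintf("Analysis of preset '%s' (%s fits, %d cells, %d failed)\n",
              x$preset, x$mode, length(x$cells), x$n_failed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Simulate and analyze a condition preset end to end
#'
#' `generate_cells` -> `compute_fretr` -> `normalize_trace` -> windowed
#' fits -> summary. Identical arguments give identical outputs. When
#' `out_dir` is given, the traces CSV, per-cell fit JSON and summary CSV
#' are written there together with a run log (preset, seed, package
#' version).
#'
#' @param preset Preset name or `gq_preset` object.
#' @param n_cells Number of cells.
#' @param seed Integer seed.
#' @param hz Optional sampling-rate override.
#' @param noise_scale Channel-noise multiplier (0 = noiseless).
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `preset_run` with the dataset, the analysis
#'   and the summary table.
#' @export
run_preset <- function(preset, n_cells = 20, seed = 1, hz = NULL,
                       noise_scale = 1, out_dir = NULL) {
  ds <- generate_cells(preset, n_cells, seed = seed, hz = hz,
                       noise_scale = noise_scale)
  an <- analyze_cells(ds)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cells(ds, out_dir)
    utils::write.csv(an$summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    fits <- lapply(Filter(Negate(is.null), an$cells), function(r) {
      out <- list(on = unclass(stats::coef(r$fit_on)), snr = r$snr$snr)
      if (!is.null(r$fit_off)) out$off <- unclass(stats::coef(r$fit_off))
      if (!is.null(r$pct)) out$pct <- r$pct
      out
    })
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log <- c(sprintf("preset: %s", ds$preset),
             sprintf("n_cells: %d  seed: %d  hz: %g", n_cells, seed,
                     ds$protocol$hz),
             sprintf("noise_sd: %.6g  noise_scale: %g", ds$noise_sd,
                     noise_scale),
             sprintf("gqfret version: %s",
                     as.character(utils::packageVersion("gqfret"))),
             sprintf("failed cells: %d", an$n_failed))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  structure(list(dataset = ds, analysis = an, summary = an$summary),
            class = "preset_run")
}

#' @export
print.preset_run <- function(x, ...) {
  print(x$analysis)
  invisible(x)
}

#' Registry of published target values
#'
#' One entry per recovery target: the condition preset, the metric of the
#' pipeline that measures it, the printed value with its SEM, and the
#' tolerance rule (`max(3 * SEM, rel_tol * value)`).
#'
#' @return A data.frame with one row per target.
#' @export
target_registry <- function() {
  path <- system.file("extdata", "targets.json", package = "gqfret")
  if (path == "") path <- file.path("inst", "extdata", "targets.json")
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  reg$targets
}

#' Recompute every registry target from a fresh simulation
#'
#' Runs the full pipeline for each target's preset (simulation, ratio
#' computation, normalization, windowed fits, summaries, dose-response
#' fit) and compares the recovered values with the registered ones under
#' the rule `|recovered - value| <= max(3 * SEM, rel_tol * value)`.
#'
#' @param seed Integer master seed; each preset derives its own stream.
#' @param n_cells Cells per condition.
#' @param registry Target table (see [target_registry()]); an empty table
#'   yields an empty passing report.
#' @param quiet Suppress progress output.
#' @return A data.frame of class `target_report`: one row per target with
#'   the simulated value, registered value, tolerance and pass flag.
#' @export
reproduce_targets <- function(seed = 1, n_cells = 20,
                              registry = target_registry(), quiet = FALSE) {
  if (is.null(registry) || nrow(registry) == 0) {
    out <- data.frame(id = character(), preset = character(),
                      metric = character(), value = numeric(),
                      n = integer(), paper = numeric(), tol = numeric(),
                      pass = logical())
    class(out) <- c("target_report", "data.frame")
    return(out)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  presets_needed <- unique(registry$preset[registry$metric != "ec50" &
                                             registry$metric != "slowdown_ratio"])
  extra <- unique(unlist(strsplit(
    registry$preset[registry$metric == "slowdown_ratio"], "/")))
  presets_needed <- unique(c(presets_needed, extra))
  runs <- list()
  for (i in seq_along(presets_needed)) {
    p <- presets_needed[i]
    say("running preset %s ...", p)
    runs[[p]] <- run_preset(p, n_cells = n_cells,
                            seed = seed + 97L * i)
  }
  mean_of <- function(preset, metric) {
    s <- runs[[preset]]$summary
    row <- s[s$metric == metric, ]
    if (nrow(row) != 1) stop("no metric ", metric, " for preset ", preset)
    c(value = row$mean, n = row$n)
  }
  rows <- lapply(seq_len(nrow(registry)), function(i) {
    e <- registry[i, ]
    if (e$metric == "ec50") {
      say("running dose series %s ...", e$preset)
      dr <- dose_response_series(e$preset, n_cells = max(10, n_cells %/% 2),
                                 seed = seed + 7919L)
      v <- c(value = dr$fit$ec50, n = nrow(dr$series))
    } else if (e$metric == "slowdown_ratio") {
      ps <- strsplit(e$preset, "/")[[1]]
      num <- mean_of(ps[1], e$numerator_metric)
      den <- mean_of(ps[2], e$numerator_metric)
      v <- c(value = unname(num["value"] / den["value"]),
             n = unname(num["n"]))
    } else {
      v <- mean_of(e$preset, e$metric)
    }
    tol <- max(3 * ifelse(is.finite(e$sem), e$sem, 0),
               e$rel_tol * e$value)
    data.frame(id = e$id, preset = e$preset, metric = e$metric,
               value = unname(v["value"]), n = as.integer(v["n"]),
               paper = e$value, tol = tol,
               pass = abs(unname(v["value"]) - e$value) <= tol)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("target_report", "data.frame")
  out
}

#' @export
print.target_report <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("Empty target registry: nothing to reproduce (pass).\n")
    return(invisible(x))
  }
  df <- as.data.frame(x)
  df$value <- signif(df$value, 4)
  df$tol <- signif(df$tol, 3)
  print(df, row.names = FALSE)
  cat(sprintf("%d/%d targets within tolerance\n", sum(x$pass), nrow(x)))
  invisible(x)
}
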