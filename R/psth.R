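#' Peri-event time histogram (PSTH)
#'
#' For each event timestamp, extracts the z trace on a uniform relative
#' grid `t in [A, B)` (step `1/sampling_rate`) by nearest-sample lookup at
#' `event + t` -- events need not fall on sample times, and no
#' interpolation smearing is introduced.  Events whose window extends
#' beyond the recording are dropped and counted.  With a baseline window
#' `[a, b]`, each trial's mean over the baseline samples is subtracted
#' from that trial before averaging (per-trial baseline correction).
#'
#' @param z an `fp_zscore` (or any `fp_timeseries`).
#' @param events an `fp_events`.
#' @param window `c(A, B)` seconds relative to the event, `A < B`.
#' @param baseline_window `c(a, b)` relative seconds inside `[A, B]`, or
#'   `NULL` for no correction.
#' @return an object of class `fp_psth`: `time` (relative grid), `trials`
#'   (n_events x N matrix), `mean`, `sem` (sd with denominator `n - 1`,
#'   divided by `sqrt(n)`), `event_name`, `baseline_window`, `n_dropped`.
#' @export
compute_psth <- function(z, events, window, baseline_window = NULL) {
  stopifnot(inherits(z, "fp_timeseries"), inherits(events, "fp_events"))
  A <- window[1]; B <- window[2]
  if (A >= B) stop("psth window must have A < B")
  if (!is.null(baseline_window)) {
    if (baseline_window[1] >= baseline_window[2])
      stop("baseline window must have a < b")
    if (baseline_window[1] < A || baseline_window[2] > B)
      stop("baseline window must lie inside the psth window [A, B]")
  }
  dt <- 1 / z$sampling_rate
  N <- round((B - A) / dt)
  rel <- A + (seq_len(N) - 1L) * dt
  t0 <- z$timestamps[1]
  n_samp <- length(z$values)
  rows <- list(); n_dropped <- 0L
  for (te in events$timestamps) {
    idx <- round((te + rel - t0) / dt) + 1L
    if (idx[1] < 1L || idx[N] > n_samp) { n_dropped <- n_dropped + 1L; next }
    rows[[length(rows) + 1L]] <- z$values[idx]
  }
  if (!length(rows))
    stop("all ", length(events$timestamps), " events fall (partly) outside ",
         "the recording; no PSTH trials")
  trials <- do.call(rbind, rows)
  if (!is.null(baseline_window)) {
    bsel <- rel >= baseline_window[1] & rel < baseline_window[2]
    if (!any(bsel)) stop("baseline window contains no grid samples")
    trials <- trials - rowMeans(trials[, bsel, drop = FALSE])
  }
  n <- nrow(trials)
  mu <- colMeans(trials)
  sem <- if (n > 1L) apply(trials, 2L, stats::sd) / sqrt(n)
         else rep(0, ncol(trials))
  structure(list(time = rel, trials = trials, mean = mu, sem = sem,
                 event_name = events$name, window = c(A, B),
                 baseline_window = baseline_window,
                 n_dropped = n_dropped,
                 sampling_rate = z$sampling_rate),
            class = "fp_psth")
}

#' @export
print.fp_psth <- function(x, ...) {
  cat(sprintf("<fp_psth> '%s': %d trials x %d samples, window [%g, %g) s%s\n",
              x$event_name, nrow(x$trials), length(x$time),
              x$window[1], x$window[2],
              if (x$n_dropped) sprintf(", %d event(s) dropped", x$n_dropped)
              else ""))
  if (!is.null(x$baseline_window))
    cat(sprintf("  baseline-corrected over [%g, %g) s\n",
                x$baseline_window[1], x$baseline_window[2]))
  invisible(x)
}

#' Mean PSTH with standard error band, plus individual trials
#'
#' @param x an `fp_psth`.
#' @param trials overlay individual trial traces in grey.
#' @export
plot.fp_psth <- function(x, trials = FALSE, ...) {
  rng <- range(x$mean + x$sem, x$mean - x$sem,
               if (trials) x$trials else NULL)
  graphics::plot(x$time, x$mean, type = "n", ylim = rng,
                 xlab = "Time from event (s)", ylab = "z-score",
                 main = x$event_name, ...)
  if (trials)
    for (i in seq_len(nrow(x$trials)))
      graphics::lines(x$time, x$trials[i, ], col = "grey80")
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$mean + x$sem, rev(x$mean - x$sem)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(x$time, x$mean, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

# trapezoidal integral of y over grid t restricted to the closed window
trapz_window <- function(t, y, win) {
  sel <- t >= win[1] - 1e-12 & t <= win[2] + 1e-12
  if (sum(sel) < 2L)
    stop("measurement window [", win[1], ", ", win[2],
         "] contains fewer than 2 grid samples")
  pracma::trapz(t[sel], y[sel])
}

check_measure_windows <- function(psth, windows) {
  if (!length(windows) || length(windows) > 5L)
    stop("between 1 and 5 measurement windows are supported (got ",
         length(windows), ")")
  for (w in windows) {
    if (length(w) != 2L || w[1] >= w[2])
      stop("each measurement window must be [start, end] with start < end")
    if (w[1] < psth$window[1] || w[2] > psth$window[2])
      stop("measurement window [", w[1], ", ", w[2],
           "] falls outside the PSTH window [",
           psth$window[1], ", ", psth$window[2], "]")
  }
  invisible(windows)
}

#' AUC and peak of the mean PSTH in user windows
#'
#' Area under the mean PSTH curve (trapezoidal rule) and its maximum, in
#' up to 5 measurement windows.  Window sample selection is on the closed
#' interval `[start, end]` so a constant trace of value `v` over a window
#' of width `w` gives AUC `v * w` exactly.
#'
#' @param psth an `fp_psth`.
#' @param windows list of `c(start, end)` pairs (relative seconds), each
#'   inside the PSTH window.
#' @return an object of class `fp_measures`: per window, `auc` (z.s),
#'   `peak` (z) and the window itself.
#' @export
measure_windows <- function(psth, windows) {
  stopifnot(inherits(psth, "fp_psth"))
  check_measure_windows(psth, windows)
  out <- lapply(windows, function(w) {
    sel <- psth$time >= w[1] - 1e-12 & psth$time <= w[2] + 1e-12
    list(window = w,
         auc = trapz_window(psth$time, psth$mean, w),
         peak = max(psth$mean[sel]))
  })
  structure(list(windows = out, event_name = psth$event_name),
            class = "fp_measures")
}

#' @export
print.fp_measures <- function(x, ...) {
  cat(sprintf("<fp_measures> '%s'\n", x$event_name))
  for (w in x$windows)
    cat(sprintf("  [%g, %g] s: AUC %.4g z.s, peak %.4g z\n",
                w$window[1], w$window[2], w$auc, w$peak))
  invisible(x)
}

#' Per-trial AUC and peak
#'
#' The same window measures applied to every trial row.  Because the
#' trapezoid is linear, the mean of per-trial AUCs equals the AUC of the
#' mean PSTH; no such identity holds for peaks (each trial's argmax may
#' differ).
#'
#' @param psth an `fp_psth`.
#' @param windows as in [measure_windows()].
#' @return list of two `n_trials x n_windows` matrices, `auc` and `peak`.
#' @export
per_trial_measures <- function(psth, windows) {
  stopifnot(inherits(psth, "fp_psth"))
  check_measure_windows(psth, windows)
  n <- nrow(psth$trials)
  auc <- matrix(NA_real_, n, length(windows))
  peak <- matrix(NA_real_, n, length(windows))
  for (j in seq_along(windows)) {
    w <- windows[[j]]
    sel <- psth$time >= w[1] - 1e-12 & psth$time <= w[2] + 1e-12
    for (i in seq_len(n)) {
      auc[i, j] <- trapz_window(psth$time, psth$trials[i, ], w)
      peak[i, j] <- max(psth$trials[i, sel])
    }
  }
  list(auc = auc, peak = peak)
}
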