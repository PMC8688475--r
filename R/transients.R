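#' Detect whole-session calcium transients
#'
#' Two-stage robust threshold on the z-score trace:
#'
#' *Stage 1* -- the trace is partitioned into consecutive windows of
#' `window_s` seconds (default 15 s; the last partial window is processed
#' as-is).  Within each window, high-amplitude samples -- values greater
#' than two raw median absolute deviations (MAD) above the window median
#' -- are filtered out.  The surviving samples over the whole session form
#' the "resultant" trace, a transient-free estimate of the noise floor.
#'
#' *Stage 2* -- with `m = median(resultant)` and `d = MAD(resultant)`,
#' strict local maxima of the full z trace exceeding `m + 3 d` are counted
#' as transients.  Amplitudes are reported as the z value at the peak.
#'
#' The window should be long relative to a single transient so each
#' window's median tracks the noise floor, not the transients themselves.
#'
#' @param z an `fp_zscore` (or any `fp_timeseries`).
#' @param window_s thresholding window in seconds (default 15).
#' @param stage2_mult multiplier on the resultant-trace MAD (default 3).
#' @return an object of class `fp_transients`: `peak_times`,
#'   `peak_amplitudes`, `mean_amplitude`, `frequency` (events/min),
#'   `threshold_trace_median`, `threshold_mad`, `duration_min`.
#' @export
detect_transients <- function(z, window_s = 15, stage2_mult = 3) {
  stopifnot(inherits(z, "fp_timeseries"))
  x <- z$values
  n <- length(x)
  dur_s <- n / z$sampling_rate
  if (window_s > dur_s)
    stop("window_s (", window_s, " s) exceeds the trace duration (",
         signif(dur_s, 6), " s)")
  w <- max(1L, round(window_s * z$sampling_rate))
  # Stage 1: per-window removal of high-amplitude samples
  keep <- logical(n)
  starts <- seq(1L, n, by = w)
  for (s in starts) {
    idx <- s:min(s + w - 1L, n)
    seg <- x[idx]
    thr <- stats::median(seg) + 2 * mad_raw(seg)
    keep[idx] <- seg <= thr
  }
  resultant <- x[keep]
  if (!length(resultant))
    stop("thresholding removed all samples; cannot estimate a noise floor")
  m <- stats::median(resultant)
  d <- mad_raw(resultant)
  # Stage 2: strict local maxima of the full trace above m + mult*d
  peaks <- local_maxima(x)
  thr2 <- m + stage2_mult * d
  hit <- peaks[x[peaks] > thr2]
  structure(list(
    peak_times = z$timestamps[hit],
    peak_amplitudes = x[hit],
    mean_amplitude = if (length(hit)) mean(x[hit]) else NaN,
    frequency = length(hit) / (dur_s / 60),
    threshold_trace_median = m,
    threshold_mad = d,
    duration_min = dur_s / 60),
    class = "fp_transients")
}

# strict local maxima; plateaus yield their first sample.  Endpoints are
# never peaks.
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  # collapse runs of equal values, compare run to neighbours
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3L) return(integer())
  i <- 2:(k - 1L)
  peak_runs <- i[r$values[i] > r$values[i - 1L] & r$values[i] > r$values[i + 1L]]
  starts[peak_runs]
}

#' Summarize a transient detection
#'
#' @param result an `fp_transients`.
#' @return list with `mean_amplitude` (z units; `NaN` with a warning when
#'   no peaks were detected) and `frequency` (events/min).
#' @export
transient_summary <- function(result) {
  stopifnot(inherits(result, "fp_transients"))
  if (!length(result$peak_amplitudes)) {
    warning("no transients detected; mean amplitude is NaN")
    return(list(mean_amplitude = NaN, frequency = 0))
  }
  list(mean_amplitude = mean(result$peak_amplitudes),
       frequency = length(result$peak_amplitudes) / result$duration_min)
}

#' @export
print.fp_transients <- function(x, ...) {
  cat(sprintf(paste0("<fp_transients> %d peaks in %.2f min ",
                     "(%.3g /min), mean amplitude %.3g z\n"),
              length(x$peak_times), x$duration_min, x$frequency,
              x$mean_amplitude))
  cat(sprintf("  noise floor: median %.3g, MAD %.3g\n",
              x$threshold_trace_median, x$threshold_mad))
  invisible(x)
}

#' Plot a z trace with detected transients marked
#'
#' @param x an `fp_transients`.
#' @param z the `fp_zscore` it was detected on.
#' @export
plot.fp_transients <- function(x, z, ...) {
  stopifnot(inherits(z, "fp_timeseries"))
  graphics::plot(z$timestamps, z$values, type = "l", xlab = "Time (s)",
                 ylab = "z-score", ...)
  graphics::points(x$peak_times, x$peak_amplitudes, col = "darkorange",
                   pch = 16, cex = 0.7)
  invisible(x)
}
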