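#' Zero-phase moving-average filter
#'
#' Applies a length-`window` uniform FIR kernel forwards and then
#' backwards over the trace (forward-backward application squares the
#' magnitude response and cancels the phase, so features are not
#' time-shifted).  Each pass reflect-pads the trace by `window` samples at
#' both ends and crops afterwards, which avoids startup transients at the
#' recording edges.  The conventional window is 100 samples and should be
#' scaled with the sampling rate.
#'
#' @param ts an `fp_timeseries`.
#' @param window kernel length in samples for one pass, `1 <= window <=
#'   length(ts)`.
#' @return filtered `fp_timeseries`; timestamps and length unchanged.
#' @export
moving_average_zero_phase <- function(ts, window = 100) {
  stopifnot(inherits(ts, "fp_timeseries"))
  window <- as.integer(window)
  n <- length(ts$values)
  if (window < 1L) stop("window must be >= 1")
  if (window > n)
    stop("filter window (", window, " samples) exceeds trace length (",
         n, " samples)")
  if (window == 1L) return(ts)
  one_pass <- function(x) {
    # reflect-pad (no edge repeat), causal moving average, crop
    m <- length(x)
    pad_l <- x[seq(min(window, m - 1L) + 1L, 2L)]
    pad_r <- x[seq(m - 1L, max(m - window, 1L))]
    xp <- c(pad_l, x, pad_r)
    f <- stats::filter(xp, rep(1 / window, window), method = "convolution",
                       sides = 1)
    as.numeric(f[(length(pad_l) + 1L):(length(pad_l) + m)])
  }
  y <- one_pass(ts$values)
  y <- rev(one_pass(rev(y)))
  time_series(ts$timestamps, y, ts$sampling_rate, validate = FALSE)
}

#' Trim the start of a recording
#'
#' Removes a fixed amount of time from the beginning of both channels
#' (useful for the light-on artifact when excitation sources switch on at
#' recording start).  Samples and event timestamps before `t0 + seconds`
#' are dropped; remaining timestamps are not shifted.
#'
#' @param session an `fp_session`.
#' @param seconds trim duration, `0 <= seconds <` recording duration.
#' @return trimmed `fp_session`.
#' @export
trim_start <- function(session, seconds) {
  stopifnot(inherits(session, "fp_session"))
  if (seconds < 0) stop("trim seconds must be >= 0")
  if (seconds == 0) return(session)
  sig <- session$signal
  cutoff <- sig$timestamps[1] + seconds
  if (cutoff >= sig$timestamps[length(sig$timestamps)])
    stop("trim of ", seconds, " s is not shorter than the recording")
  cut_ts <- function(ts) {
    keep <- ts$timestamps >= cutoff
    time_series(ts$timestamps[keep], ts$values[keep], ts$sampling_rate,
                validate = FALSE)
  }
  session$signal <- cut_ts(session$signal)
  if (!is.null(session$control)) session$control <- cut_ts(session$control)
  session$events <- lapply(session$events, function(ev)
    event_stream(ev$name, ev$timestamps[ev$timestamps >= cutoff]))
  session
}

validate_chunks <- function(keep_intervals) {
  if (!length(keep_intervals)) stop("empty chunk keep list")
  for (iv in keep_intervals)
    if (length(iv) != 2L || iv[1] >= iv[2])
      stop("each keep interval must be [start, end] with start < end")
  starts <- vapply(keep_intervals, `[[`, numeric(1), 1L)
  ends <- vapply(keep_intervals, `[[`, numeric(1), 2L)
  if (is.unsorted(starts, strictly = TRUE) || any(ends[-length(ends)] > starts[-1]))
    stop("keep intervals must be sorted and non-overlapping")
  invisible(keep_intervals)
}

#' Excise artifacts by keeping selected chunks
#'
#' Cuts both channels to the user-supplied keep intervals (half-open
#' `[start, end)` in session seconds, snapped to sample times), drops
#' events outside every keep interval, and remaps retained event
#' timestamps onto the concatenated time axis so that every event keeps
#' exactly the same sample offsets it had in the original recording.
#' Downstream, dF/F is fit per chunk and the chunks are re-joined.
#'
#' @param session an `fp_session`.
#' @param keep_intervals list of `[start, end]` pairs (seconds), sorted,
#'   non-overlapping, inside the recording's time range.
#' @return an object of class `fp_chunked`: per-chunk channel pairs, the
#'   realigned events, and concatenation bookkeeping.
#' @export
apply_chunks <- function(session, keep_intervals) {
  stopifnot(inherits(session, "fp_session"))
  validate_chunks(keep_intervals)
  sig <- session$signal
  t <- sig$timestamps
  dt <- 1 / sig$sampling_rate
  rng <- c(t[1], t[length(t)] + dt)
  chunks <- list()
  conc_start <- numeric()   # concatenated time of each chunk's first sample
  orig_start <- numeric()   # original time of each chunk's first sample
  offset <- t[1]
  for (iv in keep_intervals) {
    if (iv[1] < rng[1] - dt / 2 || iv[2] > rng[2] + dt / 2)
      stop("keep interval [", iv[1], ", ", iv[2],
           ") falls outside the recording range [",
           signif(rng[1], 6), ", ", signif(rng[2], 6), ")")
    keep <- which(t >= iv[1] & t < iv[2])
    if (length(keep) < 2L)
      stop("keep interval [", iv[1], ", ", iv[2], ") contains < 2 samples")
    cut <- function(ts) time_series(ts$timestamps[keep], ts$values[keep],
                                    ts$sampling_rate, validate = FALSE)
    chunks[[length(chunks) + 1L]] <- list(
      signal = cut(sig),
      control = if (!is.null(session$control)) cut(session$control))
    conc_start <- c(conc_start, offset)
    orig_start <- c(orig_start, t[keep[1]])
    offset <- offset + length(keep) * dt
  }
  events <- lapply(session$events, function(ev) {
    remapped <- numeric()
    for (te in ev$timestamps) {
      for (i in seq_along(chunks)) {
        if (te >= keep_intervals[[i]][1] && te < keep_intervals[[i]][2]) {
          remapped <- c(remapped, conc_start[i] + (te - orig_start[i]))
          break
        }
      }
    }
    event_stream(ev$name, remapped)
  })
  structure(list(chunks = chunks, events = events,
                 conc_start = conc_start, orig_start = orig_start,
                 sampling_rate = sig$sampling_rate,
                 original_duration = ts_duration(sig),
                 session_id = session$session_id),
            class = "fp_chunked")
}

#' Wrap an uncut session as a single chunk
#'
#' @param session an `fp_session`.
#' @return an `fp_chunked` with one chunk covering the whole recording.
#' @export
as_chunked <- function(session) {
  stopifnot(inherits(session, "fp_session"))
  t <- session$signal$timestamps
  dt <- 1 / session$signal$sampling_rate
  apply_chunks(session, list(c(t[1], t[length(t)] + dt)))
}

#' @export
print.fp_chunked <- function(x, ...) {
  n <- vapply(x$chunks, function(ch) length(ch$signal$values), integer(1))
  cat(sprintf("<fp_chunked> '%s': %d chunk(s), %s samples\n",
              x$session_id, length(x$chunks),
              paste(n, collapse = " + ")))
  invisible(x)
}

#' Exponential bleaching pseudo-control
#'
#' For recordings without an isosbestic channel: smooths the signal with
#' the zero-phase moving average, fits `f(t) = a * exp(-t / tau) + c`
#' (tau > 0) by Levenberg-Marquardt nonlinear least squares to capture the
#' slow photobleaching decay, and returns the fitted curve sampled on the
#' signal's timestamps for use as a control channel.  This corrects
#' bleaching but, unlike a recorded isosbestic channel, cannot correct
#' fast movement artifacts.
#'
#' @param signal `fp_timeseries` with at least 10 samples.
#' @param smooth_window samples for the pre-smoothing pass.
#' @return `fp_timeseries` of the fitted curve, with attribute
#'   `"coefficients"` holding `(a, tau, c)` (or `NULL` after a linear
#'   fallback).
#' @export
fit_exponential_control <- function(signal, smooth_window = 100) {
  stopifnot(inherits(signal, "fp_timeseries"))
  if (length(signal$values) < 10L)
    stop("need at least 10 samples to fit a bleaching curve")
  sm <- moving_average_zero_phase(signal,
                                  min(smooth_window, length(signal$values)))
  t0 <- sm$timestamps[1]
  tt <- sm$timestamps - t0
  v <- sm$values
  n <- length(v)
  start <- list(a = v[1] - v[n], c = v[n], tau = max(tt[n], 1e-6) / 3)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ a * exp(-tt / tau) + c,
                      start = start,
                      lower = c(a = -Inf, c = -Inf, tau = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential fit did not converge; falling back to a ",
            "degree-1 polynomial trend")
    co <- stats::lm.fit(cbind(1, tt), v)$coefficients
    fitted <- co[1] + co[2] * (signal$timestamps - t0)
    out <- time_series(signal$timestamps, fitted, signal$sampling_rate,
                       validate = FALSE)
    attr(out, "coefficients") <- NULL
    return(out)
  }
  co <- stats::coef(fit)
  fitted <- co[["a"]] * exp(-(signal$timestamps - t0) / co[["tau"]]) +
    co[["c"]]
  out <- time_series(signal$timestamps, fitted, signal$sampling_rate,
                     validate = FALSE)
  attr(out, "coefficients") <- c(a = co[["a"]], tau = co[["tau"]],
                                 c = co[["c"]])
  out
}
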