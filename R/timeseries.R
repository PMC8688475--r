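#' Uniformly sampled channel
#'
#' A `fp_timeseries` is the package's basic container: a vector of strictly
#' increasing timestamps (seconds), a vector of values (fluorescence in
#' arbitrary units, or derived units such as dF/F or z), and the sampling
#' rate in Hz.  Timestamps must be uniform to within 1% of one sample
#' period; values must be finite.
#'
#' @param timestamps numeric vector of times in seconds, strictly increasing.
#' @param values numeric vector, same length as `timestamps`, all finite.
#' @param sampling_rate sampling rate in Hz; inferred as
#'   `1 / median(diff(timestamps))` when `NULL`.
#' @param validate check invariants (length >= 2, monotone uniform
#'   timestamps, finite values).  Internal callers that construct grids
#'   arithmetically may skip it.
#' @return an object of class `fp_timeseries` with fields `timestamps`,
#'   `values`, `sampling_rate`.
#' @export
time_series <- function(timestamps, values, sampling_rate = NULL,
                        validate = TRUE) {
  timestamps <- as.numeric(timestamps)
  values <- as.numeric(values)
  if (is.null(sampling_rate)) {
    if (length(timestamps) < 2L)
      stop("need at least 2 samples to infer a sampling rate")
    sampling_rate <- 1 / stats::median(diff(timestamps))
  }
  ts <- structure(
    list(timestamps = timestamps, values = values,
         sampling_rate = as.numeric(sampling_rate)),
    class = "fp_timeseries")
  if (validate) validate_time_series(ts)
  ts
}

validate_time_series <- function(ts) {
  if (length(ts$timestamps) != length(ts$values))
    stop("timestamps and values differ in length (",
         length(ts$timestamps), " vs ", length(ts$values), ")")
  if (length(ts$values) < 2L)
    stop("time series has fewer than 2 samples")
  d <- diff(ts$timestamps)
  if (any(d <= 0))
    stop("timestamps are not strictly increasing")
  period <- 1 / ts$sampling_rate
  if (max(abs(d - period)) >= 0.01 * period)
    stop("timestamps deviate from uniform spacing by more than 1% ",
         "of the sample period (", signif(period, 6), " s)")
  if (anyNA(ts$values) || any(!is.finite(ts$values)))
    stop("values contain NA/NaN/Inf")
  invisible(ts)
}

#' @export
print.fp_timeseries <- function(x, ...) {
  cat(sprintf("<fp_timeseries> %d samples @ %.6g Hz, t = [%.6g, %.6g] s\n",
              length(x$values), x$sampling_rate,
              x$timestamps[1], x$timestamps[length(x$timestamps)]))
  invisible(x)
}

#' @export
length.fp_timeseries <- function(x) length(x$values)

ts_duration <- function(ts) length(ts$values) / ts$sampling_rate

#' Behavioral event stream
#'
#' Named, ascending event timestamps (seconds), typically TTL pulses
#' marking behavioral events synchronized with the photometry clock.
#'
#' @param name label for the event type (e.g. `"rewarded"`).
#' @param timestamps numeric vector of event times in seconds, all >= 0.
#' @return an object of class `fp_events`.
#' @export
event_stream <- function(name, timestamps) {
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop("event timestamps contain NA")
  if (length(timestamps) && any(timestamps < 0))
    stop("event timestamps must be >= 0")
  if (is.unsorted(timestamps)) timestamps <- sort(timestamps)
  structure(list(name = as.character(name), timestamps = timestamps),
            class = "fp_events")
}

#' @export
print.fp_events <- function(x, ...) {
  cat(sprintf("<fp_events> '%s': %d events\n", x$name, length(x$timestamps)))
  invisible(x)
}

#' Recording session
#'
#' Bundles the isosbestic control channel (optional), the calcium-dependent
#' signal channel, and any behavioral event streams of one recording.
#' When a control is present the two channels must cover overlapping time
#' ranges; [harmonize()] puts them on a common grid.
#'
#' @param signal `fp_timeseries`, the calcium/indicator-dependent channel.
#' @param control `fp_timeseries` or `NULL`, the isosbestic channel.
#' @param events named list of [event_stream()] objects (may be empty).
#' @param session_id label used in output file names.
#' @return an object of class `fp_session`.
#' @export
recording_session <- function(signal, control = NULL, events = list(),
                              session_id = "session") {
  stopifnot(inherits(signal, "fp_timeseries"))
  if (!is.null(control)) {
    stopifnot(inherits(control, "fp_timeseries"))
    if (control$timestamps[length(control$timestamps)] < signal$timestamps[1] ||
        signal$timestamps[length(signal$timestamps)] < control$timestamps[1])
      stop("control and signal channels do not overlap in time")
  }
  if (length(events)) {
    stopifnot(all(vapply(events, inherits, logical(1), "fp_events")))
    names(events) <- vapply(events, `[[`, character(1), "name")
  }
  structure(list(signal = signal, control = control, events = events,
                 session_id = as.character(session_id)),
            class = "fp_session")
}

#' @export
print.fp_session <- function(x, ...) {
  cat(sprintf("<fp_session> '%s'\n", x$session_id))
  cat("  signal : "); print(x$signal)
  if (!is.null(x$control)) { cat("  control: "); print(x$control) }
  else cat("  control: none (exponential pseudo-control path)\n")
  if (length(x$events))
    for (ev in x$events)
      cat(sprintf("  events : '%s' (%d)\n", ev$name, length(ev$timestamps)))
  else cat("  events : none\n")
  invisible(x)
}

# raw median absolute deviation, no 1.4826 consistency scaling
mad_raw <- function(x) stats::median(abs(x - stats::median(x)))

# population (denominator n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
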