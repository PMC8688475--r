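#' Least-squares fit of the control channel to the signal channel
#'
#' Degree-1 polynomial (ordinary least squares) fit of
#' `signal ~ slope * control + intercept`.  Scaling the control onto the
#' signal before subtraction removes the channels' different gains and
#' offsets, so that shared artifacts and bleaching cancel in the dF/F
#' step.
#'
#' @param control,signal `fp_timeseries` of equal length.
#' @return an object of class `fp_fit`: `slope`, `intercept`, and
#'   `fitted_control` (an `fp_timeseries` of `slope * control +
#'   intercept`).
#' @export
fit_control <- function(control, signal) {
  stopifnot(inherits(control, "fp_timeseries"),
            inherits(signal, "fp_timeseries"))
  x <- control$values; y <- signal$values
  if (length(x) != length(y))
    stop("control and signal differ in length; harmonize() them first")
  if (length(x) < 2L) stop("need at least 2 samples for the fit")
  if (max(x) == min(x))
    stop("control channel is constant; the degree-1 fit is degenerate. ",
         "Consider the no-isosbestic path (fit_exponential_control).")
  co <- stats::lm.fit(cbind(intercept = 1, slope = x), y)$coefficients
  slope <- unname(co["slope"]); intercept <- unname(co["intercept"])
  structure(list(
    slope = slope, intercept = intercept,
    fitted_control = time_series(control$timestamps,
                                 slope * x + intercept,
                                 control$sampling_rate, validate = FALSE)),
    class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf("<fp_fit> fitted control = %.6g * control + %.6g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Fractional fluorescence change (dF/F)
#'
#' Elementwise `(signal - fitted_control) / fitted_control`: the fitted
#' control is subtracted from the signal and the difference is normalized
#' by the fitted control, giving the fractional change from baseline
#' fluorescence.
#'
#' @param signal `fp_timeseries`.
#' @param fitted_control `fp_timeseries` of equal length; all values must
#'   be bounded away from zero (`abs(v) > eps`).
#' @param eps denominator guard in fluorescence units.
#' @param chunk_boundaries indices where excised chunks were joined
#'   (bookkeeping for chunked sessions).
#' @return an object of class `fp_dff` (an `fp_timeseries` in
#'   dimensionless dF/F units, plus `chunk_boundaries`).
#' @export
compute_dff <- function(signal, fitted_control, eps = 1e-9,
                        chunk_boundaries = integer()) {
  stopifnot(inherits(signal, "fp_timeseries"),
            inherits(fitted_control, "fp_timeseries"))
  s <- signal$values; f <- fitted_control$values
  if (length(s) != length(f))
    stop("signal and fitted control differ in length")
  bad <- which(abs(f) <= eps)
  if (length(bad))
    stop("fitted control is within ", eps, " of zero at ", length(bad),
         " sample(s) (first indices: ",
         paste(utils::head(bad, 5), collapse = ", "),
         "); dF/F is undefined there")
  structure(list(timestamps = signal$timestamps,
                 values = (s - f) / f,
                 sampling_rate = signal$sampling_rate,
                 chunk_boundaries = as.integer(chunk_boundaries)),
            class = c("fp_dff", "fp_timeseries"))
}

#' dF/F over an artifact-excised session
#'
#' Each kept chunk is fit separately -- control-to-signal least squares
#' when an isosbestic channel exists, exponential pseudo-control otherwise
#' -- and its dF/F computed; the per-chunk traces are then concatenated
#' (on the realigned time axis of [apply_chunks()]) so a single z-score
#' can be taken over the whole trace.
#'
#' @param chunked an `fp_chunked` from [apply_chunks()] / [as_chunked()].
#' @param use_isosbestic use each chunk's control channel; `FALSE` (or a
#'   session without a control) fits an exponential pseudo-control per
#'   chunk.
#' @param smooth_window pre-smoothing window for the exponential path.
#' @return an `fp_dff` whose timestamps are the concatenated axis;
#'   `chunk_boundaries` holds the first index of every chunk after the
#'   first.
#' @export
compute_dff_chunked <- function(chunked, use_isosbestic = TRUE,
                                smooth_window = 100) {
  stopifnot(inherits(chunked, "fp_chunked"))
  dt <- 1 / chunked$sampling_rate
  vals <- list(); boundaries <- integer(); n_so_far <- 0L
  for (i in seq_along(chunked$chunks)) {
    ch <- chunked$chunks[[i]]
    res <- tryCatch({
      fc <- if (use_isosbestic && !is.null(ch$control))
        fit_control(ch$control, ch$signal)$fitted_control
      else
        fit_exponential_control(ch$signal, smooth_window)
      compute_dff(ch$signal, fc)
    }, error = function(e)
      stop("chunk ", i, ": ", conditionMessage(e), call. = FALSE))
    if (i > 1L) boundaries <- c(boundaries, n_so_far + 1L)
    n_so_far <- n_so_far + length(res$values)
    vals[[i]] <- res$values
  }
  v <- unlist(vals, use.names = FALSE)
  tt <- chunked$conc_start[1] + (seq_along(v) - 1L) * dt
  structure(list(timestamps = tt, values = v,
                 sampling_rate = chunked$sampling_rate,
                 chunk_boundaries = boundaries),
            class = c("fp_dff", "fp_timeseries"))
}

#' Standardize a dF/F trace to z units
#'
#' Three conventions:
#' \describe{
#'   \item{standard}{`(x - mean(x)) / sd(x)` over the whole trace
#'     (population standard deviation, denominator `n`).}
#'   \item{baseline}{the mean and standard deviation are taken over a
#'     designated baseline period (`baseline_window`, absolute session
#'     seconds, half-open) instead of the whole trace.}
#'   \item{modified}{`0.6745 * (x - median(x)) / MAD(x)` with the raw
#'     median absolute deviation `MAD(x) = median(|x - median(x)|)`; the
#'     0.6745 factor makes the scale consistent with a standard deviation
#'     for Gaussian data.  Robust to outliers.}
#' }
#'
#' @param dff an `fp_dff` (or any `fp_timeseries`).
#' @param method `"standard"`, `"baseline"` or `"modified"`.
#' @param baseline_window `[start, end]` absolute seconds, required for
#'   `method = "baseline"`.
#' @return an object of class `fp_zscore` (an `fp_timeseries` in z units
#'   with `method` and `baseline_window` recorded).
#' @export
zscore <- function(dff, method = c("standard", "baseline", "modified"),
                   baseline_window = NULL) {
  stopifnot(inherits(dff, "fp_timeseries"))
  method <- match.arg(method)
  x <- dff$values
  if (length(x) < 2L) stop("need at least 2 samples")
  z <- switch(method,
    standard = {
      s <- sd_pop(x)
      if (s == 0) stop("constant trace: standard deviation is zero")
      (x - mean(x)) / s
    },
    baseline = {
      if (is.null(baseline_window))
        stop("method = 'baseline' requires baseline_window = c(start, end)")
      sel <- dff$timestamps >= baseline_window[1] &
        dff$timestamps < baseline_window[2]
      if (sum(sel) < 2L)
        stop("baseline window [", baseline_window[1], ", ",
             baseline_window[2], ") contains fewer than 2 samples")
      s <- sd_pop(x[sel])
      if (s == 0) stop("constant trace in baseline window")
      (x - mean(x[sel])) / s
    },
    modified = {
      m <- mad_raw(x)
      if (m == 0) stop("constant trace: median absolute deviation is zero")
      0.6745 * (x - stats::median(x)) / m
    })
  structure(list(timestamps = dff$timestamps, values = z,
                 sampling_rate = dff$sampling_rate,
                 method = method,
                 baseline_window = baseline_window,
                 chunk_boundaries = dff$chunk_boundaries),
            class = c("fp_zscore", "fp_timeseries"))
}

#' @export
print.fp_zscore <- function(x, ...) {
  cat(sprintf("<fp_zscore> method '%s', %d samples @ %.6g Hz\n",
              x$method, length(x$values), x$sampling_rate))
  invisible(x)
}

#' @export
plot.fp_dff <- function(x, ylab = expression(Delta * F / F), ...) {
  graphics::plot(x$timestamps, x$values, type = "l", xlab = "Time (s)",
                 ylab = ylab, ...)
  if (length(x$chunk_boundaries))
    graphics::abline(v = x$timestamps[x$chunk_boundaries], lty = 3,
                     col = "grey50")
  invisible(x)
}

#' @export
plot.fp_zscore <- function(x, ylab = "z-score", ...) {
  plot.fp_dff(x, ylab = ylab, ...)
}
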