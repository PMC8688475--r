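#' Parameters for a synthetic photometry session
#'
#' Defines a ground-truth recording with the structure the two-channel
#' correction assumes: a slow exponential photobleaching baseline in both
#' channels (with independent amplitude and time constant per channel, so
#' the control-to-signal fit is exercised nontrivially), movement-like
#' artifact bumps injected into BOTH channels (scaled by `artifact_gain`
#' in the signal), calcium-like transients present ONLY in the signal
#' channel, iid Gaussian noise, and named behavioral event streams.
#'
#' Defaults emulate a typical 30-minute striatal GCaMP recording: 20 Hz
#' effective per-channel rate, bleach amplitude a few hundred a.u.
#' decaying with a ~15 min time constant, transient kernel with 0.1 s
#' rise and 1 s decay (the standard calcium-indicator shape), and noise
#' at 0.5% of the bleach amplitude.
#'
#' @param duration seconds.
#' @param rate per-channel sampling rate, Hz.
#' @param bleach_signal,bleach_control `c(a, tau, c)` of
#'   `a * exp(-t/tau) + c` for each channel (a.u., s, a.u.).
#' @param artifact_events list of `c(time, amplitude, width)` Gaussian
#'   bumps (s, a.u., s) injected into both channels.
#' @param artifact_gain scalar applied to the artifact in the signal
#'   channel.  Motion artifacts scale with each channel's overall
#'   brightness, so the default matches the brightness ratio of the
#'   default bleach curves (~1.6); this proportionality is the assumption
#'   that lets the fitted isosbestic control cancel artifacts.
#' @param transient_times seconds of signal-only transients.
#' @param transient_kernel `c(amplitude, rise, decay)`: peak height
#'   (a.u.) and time constants (s) of the difference-of-exponentials
#'   kernel, normalized to unit peak before scaling.
#' @param noise_sd iid Gaussian noise sd per channel (a.u.).
#' @param behavioral_events named list of event-time vectors.
#' @param seed integer RNG seed; fixed seed gives bit-identical sessions.
#' @return an object of class `fp_synth_params`.
#' @export
synth_params <- function(duration = 1800,
                         rate = 20,
                         bleach_signal = c(a = 300, tau = 900, c = 400),
                         bleach_control = c(a = 180, tau = 1200, c = 250),
                         artifact_events = list(),
                         artifact_gain = 1.6,
                         transient_times = numeric(),
                         transient_kernel = c(amplitude = 30, rise = 0.1,
                                              decay = 1),
                         noise_sd = 1.5,
                         behavioral_events = list(),
                         seed = 1L) {
  p <- structure(list(
    duration = as.numeric(duration), rate = as.numeric(rate),
    bleach_signal = as.numeric(bleach_signal),
    bleach_control = as.numeric(bleach_control),
    artifact_events = lapply(artifact_events, as.numeric),
    artifact_gain = as.numeric(artifact_gain),
    transient_times = as.numeric(transient_times),
    transient_kernel = as.numeric(transient_kernel),
    noise_sd = as.numeric(noise_sd),
    behavioral_events = lapply(behavioral_events, as.numeric),
    seed = as.integer(seed)), class = "fp_synth_params")
  if (p$duration <= 0 || p$rate <= 0) stop("duration and rate must be > 0")
  if (p$bleach_signal[2] <= 0 || p$bleach_control[2] <= 0)
    stop("bleach time constants must be > 0")
  if (length(p$transient_times) &&
      (any(p$transient_times < 0) || any(p$transient_times >= p$duration)))
    stop("transient_times must lie in [0, duration)")
  for (a in p$artifact_events)
    if (length(a) != 3L || a[1] < 0 || a[1] >= p$duration || a[3] <= 0)
      stop("each artifact event must be c(time, amplitude, width) ",
           "with 0 <= time < duration and width > 0")
  for (ev in p$behavioral_events)
    if (length(ev) && (any(ev < 0) || any(ev >= p$duration)))
      stop("behavioral event times must lie in [0, duration)")
  if (p$transient_kernel[2] <= 0 || p$transient_kernel[3] <= 0 ||
      p$transient_kernel[2] >= p$transient_kernel[3])
    stop("transient kernel needs 0 < rise < decay")
  p
}

# difference-of-exponentials calcium kernel, normalized to unit peak
transient_kernel_shape <- function(t, rise, decay) {
  k <- exp(-t / decay) - exp(-t / rise)
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  k / (exp(-tpk / decay) - exp(-tpk / rise))
}

#' Generate a ground-truth synthetic session
#'
#' @param params an [synth_params()] object.
#' @return list with `session` (an `fp_session`) and `truth` (class
#'   `fp_ground_truth`): the clean activity trace, the artifact trace,
#'   and the generating parameters, aligned to the generated timestamps.
#' @export
generate_session <- function(params = synth_params(),
                             session_id = "synthetic") {
  stopifnot(inherits(params, "fp_synth_params"))
  n <- round(params$duration * params$rate)
  dt <- 1 / params$rate
  t <- (seq_len(n) - 1L) * dt
  bl <- function(b) b[1] * exp(-t / b[2]) + b[3]
  artifact <- numeric(n)
  for (a in params$artifact_events)
    artifact <- artifact + a[2] * exp(-0.5 * ((t - a[1]) / a[3])^2)
  activity <- numeric(n)
  kr <- params$transient_kernel
  for (te in params$transient_times) {
    i0 <- which(t >= te)[1]
    if (is.na(i0)) next
    idx <- i0:n
    activity[idx] <- activity[idx] +
      kr[1] * transient_kernel_shape(t[idx] - te, kr[2], kr[3])
  }
  noise <- with_seed(params$seed, list(
    control = stats::rnorm(n, 0, params$noise_sd),
    signal = stats::rnorm(n, 0, params$noise_sd)))
  control <- time_series(t, bl(params$bleach_control) + artifact +
                           noise$control, params$rate, validate = FALSE)
  signal <- time_series(t, bl(params$bleach_signal) +
                          params$artifact_gain * artifact + activity +
                          noise$signal, params$rate, validate = FALSE)
  events <- lapply(names(params$behavioral_events), function(nm)
    event_stream(nm, params$behavioral_events[[nm]]))
  truth <- structure(list(
    timestamps = t,
    clean_activity = activity,
    artifact = artifact,
    params = params), class = "fp_ground_truth")
  list(session = recording_session(signal, control, events, session_id),
       truth = truth)
}

#' Write a session to disk in a supported input format
#'
#' `generic_csv` writes one two-column CSV per channel
#' (`timestamps,data`) plus one single-column CSV (`timestamps`) per
#' event stream; reading the folder back with [read_generic_session()]
#' reproduces the arrays bit-identically.  `interleaved_csv` writes a
#' single camera-style multiplexed file
#' (`FrameCounter,Timestamp,LedState,Region0G`) with control and signal
#' frames alternating at twice the channel rate, plus the event CSVs;
#' read it back with [read_interleaved_session()].
#'
#' @param session an `fp_session` (control channel required for the
#'   interleaved format).
#' @param folder output folder, created if missing.
#' @param format `"generic_csv"` or `"interleaved_csv"`.
#' @return invisibly, the paths written.
#' @export
write_session <- function(session, folder,
                          format = c("generic_csv", "interleaved_csv")) {
  stopifnot(inherits(session, "fp_session"))
  format <- match.arg(format)
  dir.create(folder, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(v) sprintf("%.17g", v)
  paths <- character()
  wr_channel <- function(ts, fname) {
    p <- file.path(folder, fname)
    writeLines(c("timestamps,data",
                 paste(fmt(ts$timestamps), fmt(ts$values), sep = ",")), p)
    paths <<- c(paths, p)
  }
  if (format == "generic_csv") {
    wr_channel(session$signal, "signal.csv")
    if (!is.null(session$control)) wr_channel(session$control, "control.csv")
  } else {
    if (is.null(session$control))
      stop("interleaved format requires a control channel")
    ctl <- session$control; sig <- session$signal
    n <- min(length(ctl$values), length(sig$values))
    dt <- 1 / sig$sampling_rate
    # control frame at t, signal frame at t + dt/2
    tt <- as.vector(rbind(ctl$timestamps[seq_len(n)],
                          sig$timestamps[seq_len(n)] + dt / 2))
    vv <- as.vector(rbind(ctl$values[seq_len(n)], sig$values[seq_len(n)]))
    st <- rep(c(1L, 2L), n)
    p <- file.path(folder, "interleaved.csv")
    writeLines(c("FrameCounter,Timestamp,LedState,Region0G",
                 paste(seq_along(tt), fmt(tt), st, fmt(vv), sep = ",")), p)
    paths <- c(paths, p)
  }
  for (ev in session$events) {
    p <- file.path(folder, paste0(ev$name, ".csv"))
    writeLines(c("timestamps", fmt(ev$timestamps)), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a small ready-made demo session
#'
#' A 120 s, 20 Hz synthetic recording with bleaching, one shared
#' artifact, reward-locked transients and a `reward` event stream --
#' enough to run the full pipeline end to end.
#'
#' @param folder destination folder.
#' @param format input format to write.
#' @param seed RNG seed.
#' @return invisibly, the paths written.
#' @export
write_demo_session <- function(folder, format = "generic_csv", seed = 1L) {
  rewards <- seq(10, 110, by = 10)
  p <- synth_params(duration = 120, rate = 20,
                    artifact_events = list(c(60, 80, 0.5)),
                    transient_times = rewards + 0.5,
                    behavioral_events = list(reward = rewards),
                    seed = seed)
  gen <- generate_session(p, session_id = basename(folder))
  write_session(gen$session, folder, format)
}
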