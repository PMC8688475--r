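#' Read a session folder of per-channel CSV files
#'
#' Each channel lives in its own two-column CSV (header `timestamps,data`).
#' Any other CSV in the folder is treated as an event-timestamp file
#' (header `timestamps`) and attached as an event stream named by its
#' filename stem.
#'
#' @param folder_path session folder.
#' @param channel_map named character vector mapping roles to filenames,
#'   e.g. `c(signal = "signal.csv", control = "control.csv")`.  `signal`
#'   is required; `control` is optional (omit it for recordings without an
#'   isosbestic channel).
#' @param session_id defaults to the folder's basename.
#' @return an [recording_session()] object.
#' @export
read_generic_session <- function(folder_path, channel_map =
                                   c(signal = "signal.csv",
                                     control = "control.csv"),
                                 session_id = basename(normalizePath(folder_path))) {
  if (!dir.exists(folder_path))
    stop("session folder not found: ", folder_path)
  if (!"signal" %in% names(channel_map))
    stop("channel_map must name a 'signal' file")
  read_channel <- function(fname) {
    path <- file.path(folder_path, fname)
    if (!file.exists(path))
      stop("channel file not found: ", fname, " (in ", folder_path, ")")
    df <- utils::read.csv(path)
    if (!all(c("timestamps", "data") %in% names(df)))
      stop("channel CSV ", fname, " must have columns 'timestamps,data'")
    if (nrow(df) < 2L)
      stop("channel CSV ", fname, " has fewer than 2 samples")
    time_series(df$timestamps, df$data)
  }
  signal <- read_channel(channel_map[["signal"]])
  control <- if ("control" %in% names(channel_map) &&
                 file.exists(file.path(folder_path, channel_map[["control"]])))
    read_channel(channel_map[["control"]])
  else if ("control" %in% names(channel_map) &&
           !identical(unname(channel_map[["control"]]), "control.csv"))
    stop("channel file not found: ", channel_map[["control"]],
         " (in ", folder_path, ")")
  else NULL
  events <- discover_event_streams(folder_path, exclude = unname(channel_map))
  recording_session(signal, control, events, session_id)
}

# every CSV in the folder not claimed as a channel is an event stream
discover_event_streams <- function(folder_path, exclude = character()) {
  files <- list.files(folder_path, pattern = "\\.csv$", ignore.case = TRUE)
  files <- setdiff(files, exclude)
  events <- list()
  for (f in files) {
    df <- utils::read.csv(file.path(folder_path, f))
    if (!"timestamps" %in% names(df)) next   # not an event file
    if ("data" %in% names(df)) next          # looks like an unclaimed channel
    stem <- tools::file_path_sans_ext(f)
    events[[stem]] <- event_stream(stem, df$timestamps)
  }
  events
}

#' Read an interleaved (camera-system style) session CSV
#'
#' Some acquisition systems multiplex excitation channels into a single
#' column, marking each frame with a state/flag code (alternating LED
#' states).  Rows are partitioned by state code into per-role channels,
#' each keeping its own frame times, then [harmonize()]d onto the signal
#' channel's grid.
#'
#' @param file_path interleaved CSV with a time column, a state column and
#'   one or more region (value) columns.
#' @param state_map named vector mapping state codes to roles, e.g.
#'   `c("1" = "control", "2" = "signal")`.
#' @param region_column which value column to read; default: the first
#'   column whose name starts with `region_prefix`.
#' @param time_column,state_column,region_prefix column naming, with
#'   defaults matching common camera exports.
#' @param attach_events discover event CSVs in the file's folder.
#' @return an [recording_session()] object (channels harmonized).
#' @export
read_interleaved_session <- function(file_path,
                                     state_map = c("1" = "control",
                                                   "2" = "signal"),
                                     region_column = NULL,
                                     time_column = "Timestamp",
                                     state_column = "LedState",
                                     region_prefix = "Region",
                                     session_id = basename(dirname(normalizePath(file_path))),
                                     attach_events = TRUE) {
  if (!file.exists(file_path)) stop("interleaved file not found: ", file_path)
  df <- utils::read.csv(file_path)
  for (col in c(time_column, state_column))
    if (!col %in% names(df)) stop("column '", col, "' not found in ", file_path)
  if (is.null(region_column)) {
    hits <- grep(paste0("^", region_prefix), names(df), value = TRUE)
    if (!length(hits)) stop("no column with prefix '", region_prefix,
                            "' found in ", file_path)
    region_column <- hits[1]
  } else if (!region_column %in% names(df)) {
    stop("column '", region_column, "' not found in ", file_path)
  }
  roles <- list()
  for (code in names(state_map)) {
    rows <- df[[state_column]] == as.numeric(code)
    if (sum(rows) < 2L)
      stop("state code ", code, " has fewer than 2 frames in ", file_path)
    roles[[state_map[[code]]]] <-
      time_series(df[[time_column]][rows], df[[region_column]][rows])
  }
  if (is.null(roles$signal)) stop("state_map must assign a 'signal' role")
  if (!is.null(roles$control)) {
    h <- harmonize(roles$control, roles$signal)
    roles$control <- h[[1]]; roles$signal <- h[[2]]
  }
  events <- if (attach_events)
    discover_event_streams(dirname(file_path), exclude = basename(file_path))
  else list()
  recording_session(roles$signal, roles$control, events, session_id)
}

#' Align control and signal channels onto a common grid
#'
#' Interleaved acquisition gives the two channels offset frame times, but
#' the dF/F computation is samplewise.  Both series are restricted to
#' their overlapping time range and the control is linearly interpolated
#' onto the signal channel's timestamps; signal values on the overlap are
#' unchanged.
#'
#' @param control,signal `fp_timeseries` with overlapping time ranges.
#' @return list of two `fp_timeseries` (control, signal) with identical
#'   timestamps.
#' @export
harmonize <- function(control, signal) {
  t0 <- max(control$timestamps[1], signal$timestamps[1])
  t1 <- min(control$timestamps[length(control$timestamps)],
            signal$timestamps[length(signal$timestamps)])
  if (t0 >= t1) stop("control and signal channels do not overlap in time")
  keep <- signal$timestamps >= t0 & signal$timestamps <= t1
  tt <- signal$timestamps[keep]
  if (length(tt) < 2L) stop("fewer than 2 signal samples in the overlap")
  cv <- stats::approx(control$timestamps, control$values, xout = tt,
                      rule = 1)$y
  list(time_series(tt, cv, signal$sampling_rate, validate = FALSE),
       time_series(tt, signal$values[keep], signal$sampling_rate,
                   validate = FALSE))
}

#' Analysis parameters
#'
#' One flat bag of every tunable the pipeline uses; [read_params()] builds
#' it from a JSON or YAML config file.
#'
#' @param filter_window moving-average window in samples (per pass).
#' @param trim_start seconds removed from the start of the recording
#'   (light-on artifact).
#' @param use_isosbestic use the recorded control channel; when `FALSE`
#'   (or no control exists) an exponential pseudo-control is fit.
#' @param zscore_method one of `"standard"`, `"baseline"`, `"modified"`.
#' @param zscore_baseline_window `[start, end]` in absolute session
#'   seconds; required iff `zscore_method = "baseline"`.
#' @param transient_window thresholding window in seconds for transient
#'   detection.
#' @param psth_window `[A, B]` seconds relative to each event.
#' @param psth_baseline_window `[a, b]` relative seconds or `NULL`.
#' @param measure_windows list of up to 5 `[start, end]` relative-second
#'   pairs, each inside `psth_window`.
#' @param chunks list of `[start, end]` keep intervals in session seconds,
#'   or `NULL` to keep everything.
#' @param average_group flag consumed by [run_group()].
#' @return an object of class `fp_params`.
#' @export
analysis_parameters <- function(filter_window = 100,
                                trim_start = 0,
                                use_isosbestic = TRUE,
                                zscore_method = "standard",
                                zscore_baseline_window = NULL,
                                transient_window = 15,
                                psth_window = c(-5, 5),
                                psth_baseline_window = NULL,
                                measure_windows = list(c(0, 2)),
                                chunks = NULL,
                                average_group = FALSE) {
  p <- structure(list(
    filter_window = as.integer(filter_window),
    trim_start = as.numeric(trim_start),
    use_isosbestic = isTRUE(use_isosbestic),
    zscore_method = match.arg(zscore_method,
                              c("standard", "baseline", "modified")),
    zscore_baseline_window = if (!is.null(zscore_baseline_window))
      as.numeric(zscore_baseline_window),
    transient_window = as.numeric(transient_window),
    psth_window = as.numeric(psth_window),
    psth_baseline_window = if (!is.null(psth_baseline_window))
      as.numeric(psth_baseline_window),
    measure_windows = if (!is.null(measure_windows))
      lapply(measure_windows, as.numeric),
    chunks = if (!is.null(chunks)) lapply(chunks, as.numeric),
    average_group = isTRUE(average_group)),
    class = "fp_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (p$filter_window < 1L) stop("filter_window must be >= 1")
  if (p$trim_start < 0) stop("trim_start must be >= 0")
  if (p$transient_window <= 0) stop("transient_window must be > 0")
  if (length(p$psth_window) != 2L || p$psth_window[1] >= p$psth_window[2])
    stop("psth_window must be [A, B] with A < B")
  if (p$zscore_method == "baseline" && is.null(p$zscore_baseline_window))
    stop("zscore_method = 'baseline' requires zscore_baseline_window")
  if (!is.null(p$zscore_baseline_window) &&
      (length(p$zscore_baseline_window) != 2L ||
       p$zscore_baseline_window[1] >= p$zscore_baseline_window[2]))
    stop("zscore_baseline_window must be [start, end] with start < end")
  if (!is.null(p$psth_baseline_window)) {
    bw <- p$psth_baseline_window
    if (length(bw) != 2L || bw[1] >= bw[2])
      stop("psth_baseline_window must be [a, b] with a < b")
    if (bw[1] < p$psth_window[1] || bw[2] > p$psth_window[2])
      stop("psth_baseline_window must lie inside psth_window")
  }
  if (!is.null(p$measure_windows)) {
    if (length(p$measure_windows) > 5L)
      stop("at most 5 measure windows are supported")
    for (w in p$measure_windows) {
      if (length(w) != 2L || w[1] >= w[2])
        stop("each measure window must be [start, end] with start < end")
      if (w[1] < p$psth_window[1] || w[2] > p$psth_window[2])
        stop("measure window [", w[1], ", ", w[2],
             "] falls outside psth_window")
    }
  }
  if (!is.null(p$chunks)) validate_chunks(p$chunks)
  invisible(p)
}

#' Read an analysis parameter file (JSON or YAML)
#'
#' @param path `.json`, `.yml` or `.yaml` file holding any subset of the
#'   [analysis_parameters()] fields; unset fields take their defaults.
#' @return an `fp_params` object.
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    stop("unsupported parameter file extension: .", ext))
  known <- names(formals(analysis_parameters))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown parameter(s) in ", basename(path), ": ",
         paste(unknown, collapse = ", "))
  # chunk / measure-window lists may arrive as matrices from JSON
  for (f in c("chunks", "measure_windows"))
    if (!is.null(raw[[f]]) && is.matrix(raw[[f]]))
      raw[[f]] <- split(raw[[f]], row(raw[[f]]))
  do.call(analysis_parameters, raw)
}

# full-precision CSV so float64 arrays round-trip exactly
write_array_csv <- function(x, path) {
  fmt <- function(v) sprintf("%.17g", v)
  if (is.matrix(x)) {
    lines <- apply(x, 1L, function(r) paste(fmt(r), collapse = ","))
    header <- paste0("c", seq_len(ncol(x)), collapse = ",")
    writeLines(c(header, lines), path)
  } else {
    writeLines(c("value", fmt(as.numeric(x))), path)
  }
  path
}

read_array_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (ncol(df) == 1L) df[[1]] else as.matrix(df)
}

#' Write analysis results to disk
#'
#' Writes every array of a session analysis under the documented key
#' layout, as full-precision CSV files named `<id>_<key>.csv` (key path
#' separators become `-`), plus a JSON sidecar `<id>_attributes.json`
#' holding scalar summaries and the parameters used.  Reading a CSV back
#' with [read_array_csv] reproduces the float64 array exactly.
#'
#' @param results an `fp_analysis` object from [analyze_session()].
#' @param out_dir output directory (created if missing).
#' @param formats subset of `"csv"` (arrays) and `"json"` (attributes);
#'   both by default.
#' @return invisibly, the character vector of paths written.
#' @export
write_results <- function(results, out_dir, formats = c("csv", "json")) {
  stopifnot(inherits(results, "fp_analysis"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  probe <- file.path(out_dir, ".write_probe")
  ok <- tryCatch({ file.create(probe, showWarnings = FALSE) },
                 warning = function(w) FALSE)
  if (!isTRUE(ok)) stop("output directory not writable: ", out_dir)
  unlink(probe)

  id <- results$session_id
  paths <- character()
  put <- function(key, x) {
    p <- file.path(out_dir, paste0(id, "_", gsub("/", "-", key), ".csv"))
    write_array_csv(x, p)
    paths <<- c(paths, p)
  }
  if ("csv" %in% formats) {
    put("time", results$dff$timestamps)
    put("dff", results$dff$values)
    put("zscore", results$zscore$values)
    if (!is.null(results$transients)) {
      put("transients/peak_times", results$transients$peak_times)
      put("transients/peak_amplitudes", results$transients$peak_amplitudes)
    }
    for (ev in names(results$psth)) {
      ps <- results$psth[[ev]]
      if (nrow(ps$trials) == 0L)
        warning("PSTH for event '", ev, "' has 0 trials; writing empty matrix")
      put(paste0("psth/", ev, "/trials"), ps$trials)
      put(paste0("psth/", ev, "/time"), ps$time)
      put(paste0("psth/", ev, "/mean"), ps$mean)
      put(paste0("psth/", ev, "/sem"), ps$sem)
      ms <- results$measures[[ev]]
      if (!is.null(ms)) {
        put(paste0("measures/", ev, "/auc"),
            vapply(ms$windows, `[[`, numeric(1), "auc"))
        put(paste0("measures/", ev, "/peak"),
            vapply(ms$windows, `[[`, numeric(1), "peak"))
      }
    }
  }
  if ("json" %in% formats) {
    attrs <- list(
      session_id = id,
      parameters = unclass(results$params),
      zscore_method = results$zscore$method,
      n_samples = length(results$dff$values),
      sampling_rate = results$dff$sampling_rate)
    if (!is.null(results$transients))
      attrs <- c(attrs, list(
        mean_amplitude = results$transients$mean_amplitude,
        frequency_per_min = results$transients$frequency))
    p <- file.path(out_dir, paste0(id, "_attributes.json"))
    jsonlite::write_json(attrs, p, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
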