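#' Run the full analysis on one in-memory session
#'
#' The standard chain: zero-phase filtering of both channels, start
#' trimming, artifact-chunk excision, per-chunk control fitting and dF/F,
#' z-scoring of the concatenated trace, whole-session transient
#' statistics, and one PSTH (with window measures) per event stream.
#'
#' @param session an `fp_session`.
#' @param params an [analysis_parameters()] object.
#' @return an object of class `fp_analysis` holding `dff`, `zscore`,
#'   `transients`, `psth` (named list of `fp_psth`), `measures` (named
#'   list of `fp_measures`), `per_trial`, the parameters used, and any
#'   collected warnings.
#' @export
analyze_session <- function(session, params = analysis_parameters()) {
  stopifnot(inherits(session, "fp_session"))
  validate_params(params)
  notes <- character()
  note <- function(msg) { notes <<- c(notes, msg); warning(msg, call. = FALSE) }

  w <- min(params$filter_window, length(session$signal$values))
  session$signal <- moving_average_zero_phase(session$signal, w)
  if (!is.null(session$control))
    session$control <- moving_average_zero_phase(session$control, w)
  if (params$trim_start > 0)
    session <- trim_start(session, params$trim_start)
  chunked <- if (!is.null(params$chunks))
    apply_chunks(session, params$chunks)
  else as_chunked(session)
  use_iso <- params$use_isosbestic && !is.null(session$control)
  dff <- compute_dff_chunked(chunked, use_isosbestic = use_iso,
                             smooth_window = w)
  z <- zscore(dff, params$zscore_method,
              baseline_window = params$zscore_baseline_window)

  transients <- NULL
  if (params$transient_window <= ts_duration(z))
    transients <- detect_transients(z, params$transient_window)
  else
    note(sprintf(paste0("transient window (%g s) exceeds the trace ",
                        "duration (%.4g s); transient detection skipped"),
                 params$transient_window, ts_duration(z)))

  psth <- list(); measures <- list(); per_trial <- list()
  for (nm in names(chunked$events)) {
    ev <- chunked$events[[nm]]
    if (!length(ev$timestamps)) {
      note(sprintf("event stream '%s' has no events after trimming/chunking",
                   nm))
      next
    }
    ps <- tryCatch(
      compute_psth(z, ev, params$psth_window, params$psth_baseline_window),
      error = function(e) { note(sprintf("PSTH '%s': %s", nm,
                                         conditionMessage(e))); NULL })
    if (is.null(ps)) next
    psth[[nm]] <- ps
    if (!is.null(params$measure_windows)) {
      measures[[nm]] <- measure_windows(ps, params$measure_windows)
      per_trial[[nm]] <- per_trial_measures(ps, params$measure_windows)
    }
  }
  structure(list(session_id = session$session_id, params = params,
                 dff = dff, zscore = z, transients = transients,
                 psth = psth, measures = measures, per_trial = per_trial,
                 notes = notes),
            class = "fp_analysis")
}

#' @export
print.fp_analysis <- function(x, ...) {
  cat(sprintf("<fp_analysis> '%s'\n", x$session_id))
  cat(sprintf("  dF/F      : %d samples @ %.6g Hz\n",
              length(x$dff$values), x$dff$sampling_rate))
  cat(sprintf("  z-score   : method '%s'\n", x$zscore$method))
  if (!is.null(x$transients))
    cat(sprintf("  transients: %d (%.3g /min, mean amplitude %.3g z)\n",
                length(x$transients$peak_times), x$transients$frequency,
                x$transients$mean_amplitude))
  for (nm in names(x$psth))
    cat(sprintf("  PSTH '%s' : %d trials (%d dropped)\n", nm,
                nrow(x$psth[[nm]]$trials), x$psth[[nm]]$n_dropped))
  invisible(x)
}

#' @export
summary.fp_analysis <- function(object, ...) {
  print(object)
  for (nm in names(object$measures)) print(object$measures[[nm]])
  invisible(object)
}

#' Read a session folder, auto-detecting its format
#'
#' Folders containing an `interleaved.csv` (or any CSV with a `LedState`
#' column) are read through the interleaved path; otherwise the generic
#' per-channel path is used.
#'
#' @param folder session folder.
#' @param ... passed to the underlying reader.
#' @return an `fp_session`.
#' @export
read_session <- function(folder, ...) {
  inter <- file.path(folder, "interleaved.csv")
  if (file.exists(inter)) return(read_interleaved_session(inter, ...))
  for (f in list.files(folder, pattern = "\\.csv$", full.names = TRUE)) {
    hdr <- strsplit(readLines(f, n = 1L), ",")[[1]]
    if ("LedState" %in% hdr) return(read_interleaved_session(f, ...))
  }
  read_generic_session(folder, ...)
}

#' Analyze one or more session folders (single or batch processing)
#'
#' One folder runs single processing; several folders run batch
#' processing, where each folder is analyzed independently and a failure
#' in one is logged and skipped while the others complete.
#'
#' @param config an `fp_params` object or the path of a JSON/YAML
#'   parameter file.
#' @param session_folders character vector of session folders.
#' @param out_dir root output directory; each session writes into
#'   `out_dir/<session_id>/`.  Defaults to an `output` subfolder inside
#'   each session folder.
#' @param formats passed to [write_results()].
#' @return an object of class `fp_manifest`: per-folder outputs, collected
#'   warnings, failures, software version and timestamp.  `ok` is `FALSE`
#'   when any folder failed.
#' @export
run_analyze <- function(config, session_folders, out_dir = NULL,
                        formats = c("csv", "json")) {
  params <- if (inherits(config, "fp_params")) config else read_params(config)
  missing <- session_folders[!dir.exists(session_folders)]
  if (length(missing))
    stop("session folder(s) not found: ", paste(missing, collapse = ", "))
  outputs <- list(); failures <- character(); warnings_log <- character()
  analyses <- list()
  for (folder in session_folders) {
    res <- tryCatch({
      session <- read_session(folder)
      withCallingHandlers(
        analysis <- analyze_session(session, params),
        warning = function(w) {
          warnings_log <<- c(warnings_log,
                             paste0(basename(folder), ": ",
                                    conditionMessage(w)))
          invokeRestart("muffleWarning")
        })
      dest <- if (is.null(out_dir)) file.path(folder, "output")
              else file.path(out_dir, analysis$session_id)
      paths <- write_results(analysis, dest, formats)
      analyses[[analysis$session_id]] <- analysis
      list(ok = TRUE, paths = paths)
    }, error = function(e) list(ok = FALSE, err = conditionMessage(e)))
    if (res$ok) outputs[[folder]] <- res$paths
    else failures[folder] <- res$err
  }
  structure(list(session_folders = session_folders, outputs = outputs,
                 failures = failures, warnings = warnings_log,
                 analyses = analyses,
                 params = params,
                 version = as.character(utils::packageVersion("photometr")),
                 timestamp = format(Sys.time(), tz = "UTC"),
                 ok = !length(failures)),
            class = "fp_manifest")
}

#' @export
print.fp_manifest <- function(x, ...) {
  cat(sprintf("<fp_manifest> %d folder(s), %d ok, %d failed (v%s)\n",
              length(x$session_folders), length(x$outputs),
              length(x$failures), x$version))
  for (f in names(x$failures))
    cat("  FAILED ", f, ": ", x$failures[[f]], "\n", sep = "")
  invisible(x)
}

#' Group-average previously analyzed sessions
#'
#' Takes the manifest of a [run_analyze()] batch, averages the sessions'
#' PSTHs and window measures per event (see [average_group()]), and
#' writes the group arrays under `out_dir` with file prefix `group`.
#'
#' @param manifest an `fp_manifest` with at least one successful session.
#' @param out_dir output directory for the group CSVs.
#' @param events event names to average; default: events present in every
#'   session.
#' @return named list of `fp_group`, one per event.
#' @export
run_group <- function(manifest, out_dir = NULL, events = NULL) {
  stopifnot(inherits(manifest, "fp_manifest"))
  analyses <- manifest$analyses
  if (!length(analyses))
    stop("no successfully analyzed sessions in the manifest; run_analyze ",
         "must succeed first (failed: ",
         paste(names(manifest$failures), collapse = ", "), ")")
  if (is.null(events)) {
    events <- Reduce(intersect, lapply(analyses, function(a) names(a$psth)))
    if (!length(events))
      stop("no event stream is present in every session")
  }
  fmt <- function(v) sprintf("%.17g", v)
  out <- list()
  for (ev in events) {
    res <- lapply(analyses, function(a) a$psth[[ev]])
    ms <- lapply(analyses, function(a) a$measures[[ev]])
    if (any(vapply(ms, is.null, logical(1)))) ms <- NULL
    g <- average_group(res, ms, session_ids = names(analyses))
    out[[ev]] <- g
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      base <- file.path(out_dir, paste0("group_", ev))
      write_array_csv(g$time, paste0(base, "_time.csv"))
      write_array_csv(g$session_means, paste0(base, "_session-means.csv"))
      write_array_csv(g$group_mean, paste0(base, "_mean.csv"))
      write_array_csv(g$group_sem, paste0(base, "_sem.csv"))
      if (!is.null(g$measures))
        jsonlite::write_json(g$measures, paste0(base, "_measures.json"),
                             auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  out
}

#' Export static figures for an analysis or group result
#'
#' @param x an `fp_analysis` or `fp_group`.
#' @param out_dir destination directory.
#' @param devices subset of `"png"`, `"svg"`, `"pdf"`.
#' @return invisibly, the files written.
#' @export
export_plots <- function(x, out_dir, devices = "png") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  open_dev <- function(path, dev) switch(dev,
    png = grDevices::png(path, width = 900, height = 500),
    svg = grDevices::svg(path, width = 9, height = 5),
    pdf = grDevices::pdf(path, width = 9, height = 5),
    stop("unknown device: ", dev))
  files <- character()
  draw <- function(stem, fun) {
    for (dev in devices) {
      path <- file.path(out_dir, paste0(stem, ".", dev))
      open_dev(path, dev)
      tryCatch(fun(), finally = grDevices::dev.off())
      files <<- c(files, path)
    }
  }
  if (inherits(x, "fp_analysis")) {
    draw(paste0(x$session_id, "_dff"), function() plot(x$dff))
    draw(paste0(x$session_id, "_zscore"), function() plot(x$zscore))
    if (!is.null(x$transients))
      draw(paste0(x$session_id, "_transients"),
           function() plot(x$transients, x$zscore))
    for (nm in names(x$psth))
      draw(paste0(x$session_id, "_psth_", nm),
           function() plot(x$psth[[nm]], trials = TRUE))
  } else if (inherits(x, "fp_group")) {
    draw(paste0("group_", x$event_name), function() plot(x))
  } else stop("cannot plot object of class ", class(x)[1])
  invisible(files)
}
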