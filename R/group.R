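#' Average PSTHs across sessions or animals
#'
#' Each session contributes its mean PSTH as one trace, regardless of how
#' many trials it contains (equal weighting -- one animal, one vote -- so
#' high-trial sessions cannot dominate the group average).  Window
#' measures are averaged the same way.  All sessions must share the event
#' name and an identical relative time grid; mismatches are an error, not
#' silently resampled.
#'
#' @param results list of `fp_psth`, one per session.
#' @param measures optional list of `fp_measures`, parallel to `results`.
#' @param session_ids labels; default `session_1 ... session_n`.
#' @return an object of class `fp_group`: `time`, `session_means`
#'   (n_sessions x N), `group_mean`, `group_sem` (sd/(sqrt n) across
#'   sessions; 0 with a warning when n = 1), `measures` (per window:
#'   per-session values plus group mean +/- sem), `session_ids`.
#' @export
average_group <- function(results, measures = NULL, session_ids = NULL) {
  if (!length(results)) stop("need at least 1 session")
  stopifnot(all(vapply(results, inherits, logical(1), "fp_psth")))
  if (is.null(session_ids))
    session_ids <- paste0("session_", seq_along(results))
  ref <- results[[1]]
  for (i in seq_along(results)) {
    r <- results[[i]]
    if (!identical(r$event_name, ref$event_name))
      stop("event name mismatch: session ", session_ids[i], " has '",
           r$event_name, "', expected '", ref$event_name, "'")
    if (length(r$time) != length(ref$time) ||
        max(abs(r$time - ref$time)) > 1e-9)
      stop("relative time grid mismatch in session(s): ", session_ids[i])
  }
  sm <- do.call(rbind, lapply(results, `[[`, "mean"))
  n <- nrow(sm)
  gmean <- colMeans(sm)
  gsem <- if (n > 1L) apply(sm, 2L, stats::sd) / sqrt(n)
  else {
    warning("group of a single session; SEM reported as 0")
    rep(0, ncol(sm))
  }
  gm <- NULL
  if (!is.null(measures)) {
    stopifnot(length(measures) == length(results),
              all(vapply(measures, inherits, logical(1), "fp_measures")))
    nw <- length(measures[[1]]$windows)
    gm <- lapply(seq_len(nw), function(j) {
      aucs <- vapply(measures, function(m) m$windows[[j]]$auc, numeric(1))
      peaks <- vapply(measures, function(m) m$windows[[j]]$peak, numeric(1))
      list(window = measures[[1]]$windows[[j]]$window,
           auc = aucs, peak = peaks,
           auc_mean = mean(aucs),
           auc_sem = if (n > 1L) stats::sd(aucs) / sqrt(n) else 0,
           peak_mean = mean(peaks),
           peak_sem = if (n > 1L) stats::sd(peaks) / sqrt(n) else 0)
    })
  }
  structure(list(time = ref$time, session_means = sm, group_mean = gmean,
                 group_sem = gsem, measures = gm,
                 event_name = ref$event_name, session_ids = session_ids),
            class = "fp_group")
}

#' @export
print.fp_group <- function(x, ...) {
  cat(sprintf("<fp_group> '%s': %d sessions x %d samples\n",
              x$event_name, nrow(x$session_means), length(x$time)))
  invisible(x)
}

#' @export
plot.fp_group <- function(x, ...) {
  rng <- range(x$group_mean + x$group_sem, x$group_mean - x$group_sem,
               x$session_means)
  graphics::plot(x$time, x$group_mean, type = "n", ylim = rng,
                 xlab = "Time from event (s)", ylab = "z-score",
                 main = paste0(x$event_name, " (group, n = ",
                               nrow(x$session_means), ")"), ...)
  for (i in seq_len(nrow(x$session_means)))
    graphics::lines(x$time, x$session_means[i, ], col = "grey75")
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$group_mean + x$group_sem,
                      rev(x$group_mean - x$group_sem)),
                    col = grDevices::adjustcolor("firebrick", 0.25),
                    border = NA)
  graphics::lines(x$time, x$group_mean, lwd = 2)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
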