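# small builders shared across the suite

make_ts <- function(values, rate = 10, t0 = 0) {
  n <- length(values)
  time_series(t0 + (seq_len(n) - 1) / rate, values, rate)
}

# a clean event-locked session: flat bleach-free channels plus one
# transient exactly `latency` seconds after every event
event_locked_session <- function(events, latency = 1, duration = 60,
                                 rate = 20, noise_sd = 0, seed = 11,
                                 amplitude = 30) {
  p <- synth_params(duration = duration, rate = rate,
                    transient_times = events + latency,
                    transient_kernel = c(amplitude, 0.1, 1),
                    noise_sd = noise_sd,
                    behavioral_events = list(stim = events),
                    seed = seed)
  generate_session(p)
}

write_generic_fixture <- function(dir, rate = 10, n = 30,
                                  control = rep(1, n), signal = rep(2, n),
                                  events = list(rewarded = 0.1)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  t <- (seq_len(n) - 1) / rate
  writeLines(c("timestamps,data", paste(t, control, sep = ",")),
             file.path(dir, "control.csv"))
  writeLines(c("timestamps,data", paste(t, signal, sep = ",")),
             file.path(dir, "signal.csv"))
  for (nm in names(events))
    writeLines(c("timestamps", as.character(events[[nm]])),
               file.path(dir, paste0(nm, ".csv")))
  dir
}
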