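test_that("the moving-average filter preserves constants and window 1 is identity", {
  ts <- make_ts(rep(5, 50))
  for (w in c(2, 7, 10))
    expect_equal(moving_average_zero_phase(ts, w)$values, rep(5, 50),
                 tolerance = 1e-12)
  expect_identical(moving_average_zero_phase(ts, 1)$values, ts$values)
  expect_error(moving_average_zero_phase(ts, 51), "51")
})

test_that("forward-backward filtering is zero-phase on a symmetric pulse", {
  n <- 101; k <- 51
  pulse <- pmax(0, 10 - abs(seq_len(n) - k))  # triangle centered at k
  ts <- make_ts(pulse)
  out <- moving_average_zero_phase(ts, 7)$values
  expect_equal(which.max(out), k)
  # brute-force cross-correlation peaks at lag 0
  lags <- -10:10
  cc <- vapply(lags, function(L) {
    i <- seq_len(n); j <- i + L
    ok <- j >= 1 & j <= n
    sum(pulse[i[ok]] * out[j[ok]])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  # argmax stays put for other odd windows too
  for (w in c(3, 5, 9, 11))
    expect_equal(which.max(moving_average_zero_phase(ts, w)$values), k)
})

test_that("the filter is linear", {
  withr::local_seed(5)
  x <- rnorm(200); y <- rnorm(200)
  f <- function(v, w = 9) moving_average_zero_phase(make_ts(v), w)$values
  expect_equal(f(2.5 * x - 1.3 * y), 2.5 * f(x) - 1.3 * f(y),
               tolerance = 1e-10)
})

test_that("trim_start removes samples and events before the cutoff, unshifted", {
  t <- (0:99) / 10
  sig <- time_series(t, seq_along(t), 10)
  ctl <- time_series(t, rev(seq_along(t)), 10)
  ses <- recording_session(sig, ctl,
                           list(event_stream("ev", c(0.5, 1.5))), "s1")
  expect_identical(trim_start(ses, 0), ses)
  tr <- trim_start(ses, 1)
  expect_length(tr$signal$values, 90)
  expect_equal(tr$signal$timestamps[1], 1.0)
  expect_equal(tr$control$timestamps[1], 1.0)
  expect_equal(tr$events$ev$timestamps, 1.5)  # 0.5 dropped, 1.5 unshifted
  expect_error(trim_start(ses, 10), "recording")
})

test_that("chunk excision cuts both channels, drops and remaps events", {
  t <- (0:299) / 10  # 30 s at 10 Hz
  ses <- recording_session(
    time_series(t, sin(t), 10), time_series(t, cos(t), 10),
    list(event_stream("ev", c(5, 15, 25))), "s1")
  # identity chunking: one interval spanning everything
  ch0 <- as_chunked(ses)
  expect_length(ch0$chunks, 1)
  expect_identical(ch0$chunks[[1]]$signal$values, sin(t))
  expect_equal(ch0$events$ev$timestamps, c(5, 15, 25))
  # keep [0,10) and [20,30): event at 15 dropped, event at 25 -> 15
  ch <- apply_chunks(ses, list(c(0, 10), c(20, 30)))
  expect_length(ch$chunks, 2)
  expect_equal(ch$events$ev$timestamps, c(5, 15))
  # conservation of samples inside keep intervals
  n_in <- sum(t >= 0 & t < 10) + sum(t >= 20 & t < 30)
  expect_equal(sum(vapply(ch$chunks,
                          function(c) length(c$signal$values), integer(1))),
               n_in)
  # dropped events are exactly those outside all keep intervals
  expect_equal(length(ses$events$ev$timestamps) -
                 length(ch$events$ev$timestamps), 1L)
  expect_error(apply_chunks(ses, list()), "empty")
  expect_error(apply_chunks(ses, list(c(25, 40))), "outside")
})

test_that("chunk excision preserves event-to-sample alignment exactly", {
  # transient exactly 1 s after each event; excise a quiet middle stretch
  events <- c(10, 50)
  gen <- event_locked_session(events, latency = 1, duration = 60,
                              rate = 20, noise_sd = 0)
  ses <- gen$session
  z_full <- zscore(compute_dff_chunked(as_chunked(ses)), "standard")
  ps_full <- compute_psth(z_full, ses$events$stim, c(-2, 3))
  ch <- apply_chunks(ses, list(c(0, 20), c(40, 60)))
  z_cut <- zscore(compute_dff_chunked(ch), "standard")
  ps_cut <- compute_psth(z_cut, ch$events$stim, c(-2, 3))
  expect_equal(ps_cut$time, ps_full$time)
  # same sample offsets relative to each event: peak in the same column
  expect_equal(which.max(ps_cut$mean), which.max(ps_full$mean))
  # kernel (rise 0.1 s, decay 1 s) peaks log(10)/9 s after onset
  t_peak <- 1 + 0.1 * 1 / (1 - 0.1) * log(1 / 0.1)
  expect_equal(ps_full$time[which.max(ps_full$mean)], t_peak,
               tolerance = 0.06)
})

test_that("the exponential pseudo-control recovers bleaching parameters", {
  rate <- 10
  t <- (0:1999) / rate  # 200 s
  bleach <- 2 * exp(-t / 100) + 1
  # noiseless: (a, tau, c) within 0.1%
  fit <- fit_exponential_control(time_series(t, bleach, rate),
                                 smooth_window = 1)
  co <- attr(fit, "coefficients")
  expect_equal(unname(co["a"]), 2, tolerance = 1e-3)
  expect_equal(unname(co["tau"]), 100, tolerance = 1e-3)
  expect_equal(unname(co["c"]), 1, tolerance = 1e-3)
  expect_equal(fit$values, bleach, tolerance = 1e-6)
  # 1% (of a) Gaussian noise: tau within 5%
  withr::local_seed(21)
  noisy <- bleach + rnorm(length(t), 0, 0.02)
  fit2 <- fit_exponential_control(time_series(t, noisy, rate),
                                  smooth_window = 100)
  expect_equal(unname(attr(fit2, "coefficients")["tau"]), 100,
               tolerance = 0.05)
  # constant input: returned curve is flat
  flat <- suppressWarnings(
    fit_exponential_control(make_ts(rep(3, 100)), smooth_window = 10))
  expect_equal(flat$values, rep(3, 100), tolerance = 1e-6 * 3)
})
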