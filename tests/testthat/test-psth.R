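test_that("a constant trace gives constant trials; baseline correction zeroes them", {
  z <- make_ts(rep(5, 600), rate = 10)  # 60 s
  ev <- event_stream("cue", c(10, 25, 40))
  ps <- compute_psth(z, ev, c(-2, 2))
  expect_equal(dim(ps$trials), c(3L, 40L))
  expect_true(all(ps$trials == 5))
  expect_equal(ps$sem, rep(0, 40))
  psb <- compute_psth(z, ev, c(-2, 2), baseline_window = c(-2, 0))
  expect_true(all(psb$trials == 0))
  expect_true(all(psb$mean == 0))
})

test_that("baseline-corrected trials average exactly zero over the baseline", {
  gen <- event_locked_session(c(10, 20, 30, 40), duration = 60,
                              noise_sd = 1.5, seed = 13)
  a_z <- zscore(compute_dff_chunked(as_chunked(gen$session)), "standard")
  ps <- compute_psth(a_z, gen$session$events$stim, c(-2, 3),
                     baseline_window = c(-2, 0))
  bsel <- ps$time >= -2 & ps$time < 0
  expect_equal(unname(rowMeans(ps$trials[, bsel])), rep(0, nrow(ps$trials)),
               tolerance = 1e-10)
  # mean/sem definitions
  expect_equal(ps$mean, colMeans(ps$trials), tolerance = 1e-12)
  expect_equal(ps$sem, apply(ps$trials, 2, sd) / sqrt(nrow(ps$trials)),
               tolerance = 1e-12)
})

test_that("an event-locked kernel peaks at its true latency in the mean PSTH", {
  events <- seq(10, 110, by = 10)
  gen <- event_locked_session(events, latency = 1, duration = 120,
                              rate = 20, noise_sd = 1, seed = 17)
  z <- zscore(compute_dff_chunked(as_chunked(gen$session)), "standard")
  ps <- compute_psth(z, gen$session$events$stim, c(-2, 4))
  t_peak <- 1 + 0.1 / 0.9 * log(10)
  expect_equal(ps$time[which.max(ps$mean)], t_peak, tolerance = 0.051)
})

test_that("events whose windows leave the recording are dropped and counted", {
  z <- make_ts(rnorm(200), rate = 10)  # 20 s
  ev <- event_stream("cue", c(0.5, 10, 19.5))
  ps <- compute_psth(z, ev, c(-2, 2))
  expect_equal(nrow(ps$trials), 1L)
  expect_equal(ps$n_dropped, 2L)
  expect_equal(nrow(ps$trials) + ps$n_dropped, 3L)
  expect_error(compute_psth(z, event_stream("cue", 100), c(-2, 2)), "outside")
  expect_error(compute_psth(z, ev, c(2, -2)), "A < B")
})

test_that("the PSTH is equivariant under a common time translation", {
  withr::local_seed(23)
  v <- rnorm(600)
  z1 <- time_series((0:599) / 10, v, 10)
  z2 <- time_series(7.3 + (0:599) / 10, v, 10)
  ev1 <- event_stream("e", c(15, 30, 45))
  ev2 <- event_stream("e", c(15, 30, 45) + 7.3)
  ps1 <- compute_psth(z1, ev1, c(-1, 2))
  ps2 <- compute_psth(z2, ev2, c(-1, 2))
  expect_equal(ps1$trials, ps2$trials)
  expect_equal(ps1$mean, ps2$mean)
})

test_that("window measures reproduce analytic areas and peaks", {
  # rectangle: constant 2 over a width-3 window
  t <- seq(-1, 3.9, by = 0.1)
  mk <- function(vals, A = -1, B = 4) structure(
    list(time = t, trials = rbind(vals), mean = vals,
         sem = rep(0, length(t)), event_name = "e", window = c(A, B),
         baseline_window = NULL, n_dropped = 0L, sampling_rate = 10),
    class = "fp_psth")
  m <- measure_windows(mk(rep(2, length(t))), list(c(0, 3)))
  expect_equal(m$windows[[1]]$auc, 6, tolerance = 1e-12)
  expect_equal(m$windows[[1]]$peak, 2)
  # affine: mean = t on [0, 1], dt = 0.1 -> exactly 0.5
  m2 <- measure_windows(mk(pmax(t, 0) * (t <= 1)), list(c(0, 1)))
  expect_equal(m2$windows[[1]]$auc, 0.5, tolerance = 1e-12)
  # sin on [0, pi], dt = 0.01: within dt^2 of the analytic integral 2
  ts2 <- seq(0, pi, by = 0.01)
  ps2 <- structure(list(time = ts2, trials = rbind(sin(ts2)),
                        mean = sin(ts2), sem = rep(0, length(ts2)),
                        event_name = "e", window = c(0, pi),
                        baseline_window = NULL, n_dropped = 0L,
                        sampling_rate = 100), class = "fp_psth")
  m3 <- measure_windows(ps2, list(c(0, pi)))
  expect_equal(m3$windows[[1]]$auc, 2, tolerance = 0.01^2)
  # guards: > 5 windows, window outside [A, B]
  expect_error(measure_windows(ps2, rep(list(c(0, 1)), 6)), "5")
  expect_error(measure_windows(ps2, list(c(-1, 1))), "outside")
})

test_that("per-trial AUCs average to the AUC of the mean PSTH", {
  # two constant trials 1 and 3 over a width-2 window
  t <- seq(-1, 2.9, by = 0.1)
  tr <- rbind(rep(1, length(t)), rep(3, length(t)))
  ps <- structure(list(time = t, trials = tr, mean = colMeans(tr),
                       sem = rep(0, length(t)), event_name = "e",
                       window = c(-1, 3), baseline_window = NULL,
                       n_dropped = 0L, sampling_rate = 10),
                  class = "fp_psth")
  pt <- per_trial_measures(ps, list(c(0, 2)))
  expect_equal(pt$auc[, 1], c(2, 6))
  expect_equal(mean(pt$auc[, 1]),
               measure_windows(ps, list(c(0, 2)))$windows[[1]]$auc,
               tolerance = 1e-12)
  # random trial matrix: linearity of the trapezoid, brute force
  withr::local_seed(5)
  tr2 <- matrix(rnorm(20 * length(t)), 20)
  ps2 <- ps; ps2$trials <- tr2; ps2$mean <- colMeans(tr2)
  pt2 <- per_trial_measures(ps2, list(c(-1, 1), c(0, 2.5)))
  mw2 <- measure_windows(ps2, list(c(-1, 1), c(0, 2.5)))
  for (j in 1:2)
    expect_equal(mean(pt2$auc[, j]), mw2$windows[[j]]$auc,
                 tolerance = 1e-10)
})
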