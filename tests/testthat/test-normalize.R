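test_that("the degree-1 control fit recovers affine relations", {
  t <- (0:99) / 10
  ctl <- time_series(t, 1 + 0.3 * sin(t), 10)
  # identity
  f0 <- fit_control(ctl, ctl)
  expect_equal(f0$slope, 1, tolerance = 1e-10)
  expect_equal(f0$intercept, 0, tolerance = 1e-10)
  # exact affine relation
  sig <- time_series(t, 3 * ctl$values + 2, 10)
  f1 <- fit_control(ctl, sig)
  expect_equal(f1$slope, 3, tolerance = 1e-10)
  expect_equal(f1$intercept, 2, tolerance = 1e-10)
  expect_equal(f1$fitted_control$values,
               f1$slope * ctl$values + f1$intercept, tolerance = 1e-12)
  # constant control is degenerate
  expect_error(fit_control(make_ts(rep(1, 100)), make_ts(rnorm(100))),
               "constant")
})

test_that("the noisy control fit matches the closed-form least-squares oracle", {
  withr::local_seed(101)
  n <- 10000
  x <- runif(n, 0.5, 1.5)
  y <- 2 * x + 1 + rnorm(n, 0, 0.01)
  rate <- 10; t <- (seq_len(n) - 1) / rate
  f <- fit_control(time_series(t, x, rate), time_series(t, y, rate))
  # scalar closed form: slope = cov/var, intercept = ybar - slope xbar
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  expect_equal(f$slope, sl, tolerance = 1e-12)
  expect_equal(f$intercept, ic, tolerance = 1e-12)
  expect_true(f$slope > 1.99 && f$slope < 2.01)
})

test_that("dF/F equals its elementwise definition", {
  # equality gives zeros
  ts1 <- make_ts(rep(1.0, 20))
  expect_equal(compute_dff(ts1, ts1)$values, rep(0, 20))
  # direct substitution
  expect_equal(compute_dff(make_ts(rep(1.1, 20)), ts1)$values,
               rep(0.1, 20), tolerance = 1e-15)
  # scalar-loop oracle on random positive pairs
  withr::local_seed(7)
  s <- runif(500, 0.5, 2); f <- runif(500, 0.5, 2)
  got <- compute_dff(make_ts(s), make_ts(f))$values
  want <- numeric(500)
  for (i in 1:500) want[i] <- (s[i] - f[i]) / f[i]
  expect_equal(got, want, tolerance = 1e-15)
  # denominator guard
  f[17] <- 0
  expect_error(compute_dff(make_ts(s), make_ts(f)), "17")
})

test_that("dF/F is invariant to a common positive rescaling", {
  withr::local_seed(8)
  s <- runif(300, 1, 2); f <- runif(300, 1, 2)
  base <- compute_dff(make_ts(s), make_ts(f))$values
  for (k in c(0.1, 3, 1000))
    expect_equal(compute_dff(make_ts(k * s), make_ts(k * f))$values, base,
                 tolerance = 1e-12)
})

test_that("chunked dF/F reduces to the whole-trace computation for one chunk", {
  gen <- event_locked_session(c(5, 15), duration = 30, noise_sd = 1, seed = 5)
  ses <- gen$session
  whole <- compute_dff(ses$signal,
                       fit_control(ses$control, ses$signal)$fitted_control)
  one <- compute_dff_chunked(as_chunked(ses))
  expect_equal(one$values, whole$values, tolerance = 1e-12)
  expect_length(one$chunk_boundaries, 0)
})

test_that("per-chunk fitting leaves no step at the join of a clean signal", {
  p <- synth_params(duration = 120, rate = 20,
                    bleach_signal = c(300, 300, 400),
                    bleach_control = c(180, 500, 250),
                    noise_sd = 0.5, seed = 9)
  ses <- generate_session(p)$session
  ch <- apply_chunks(ses, list(c(0, 60), c(60, 120)))
  dff <- compute_dff_chunked(ch)
  j <- dff$chunk_boundaries[1]
  local_sd <- stats::sd(diff(dff$values[(j - 200):(j - 1)]))
  step <- abs(dff$values[j] - dff$values[j - 1])
  expect_lt(step, 5 * local_sd)
})

test_that("excising an artifact chunk restores the clean dF/F range", {
  base <- synth_params(duration = 120, rate = 20, noise_sd = 0.5,
                       transient_times = c(20, 40, 80, 100), seed = 12)
  clean <- generate_session(base)$session
  dirty_p <- base
  dirty_p$artifact_events <- list(c(65, 400, 1.0))  # huge mid-session artifact
  dirty <- generate_session(dirty_p)$session
  rng <- function(dff) diff(range(dff$values))
  r_clean <- rng(compute_dff_chunked(as_chunked(clean)))
  r_cut <- rng(compute_dff_chunked(
    apply_chunks(dirty, list(c(0, 60), c(72, 120)))))
  expect_equal(r_cut, r_clean, tolerance = 0.1)
})

test_that("z-score conventions match their definitions", {
  withr::local_seed(3)
  x <- rnorm(1000, 5, 2)
  z <- zscore(make_ts(x), "standard")$values
  expect_equal(mean(z), 0, tolerance = 1e-10)
  expect_equal(sqrt(mean((z - mean(z))^2)), 1, tolerance = 1e-10)
  # population (denominator n) convention, against a scalar-loop oracle
  mu <- sum(x) / length(x)
  ss <- 0; for (v in x) ss <- ss + (v - mu)^2
  sd_n <- sqrt(ss / length(x))
  expect_equal(z, (x - mu) / sd_n, tolerance = 1e-12)
  # baseline method uses the designated window's mean and sd
  t <- (seq_along(x) - 1) / 10
  zb <- zscore(time_series(t, x, 10), "baseline",
               baseline_window = c(0, 10))$values
  sel <- t >= 0 & t < 10
  mub <- mean(x[sel]); sdb <- sqrt(mean((x[sel] - mub)^2))
  expect_equal(zb, (x - mub) / sdb, tolerance = 1e-12)
  # modified z on (0, 1, 2): median 1, MAD 1, scaled by 0.6745
  ts3 <- time_series(c(0, 0.1, 0.2), c(0, 1, 2), 10)
  expect_equal(zscore(ts3, "modified")$values, c(-0.6745, 0, 0.6745))
  expect_error(zscore(make_ts(rep(2, 10)), "standard"), "constant")
  expect_error(zscore(make_ts(rep(2, 10)), "modified"), "constant")
})

test_that("modified and standard z agree in scale for Gaussian data", {
  withr::local_seed(2024)
  x <- rnorm(1e5)
  ts <- make_ts(x, rate = 100)
  zs <- zscore(ts, "standard")$values
  zm <- zscore(ts, "modified")$values
  slope <- sum(zs * zm) / sum(zs^2)
  expect_gt(slope, 0.98); expect_lt(slope, 1.02)
})

test_that("all z-score methods are invariant to positive affine input maps", {
  withr::local_seed(31)
  x <- rnorm(500)
  t <- (seq_along(x) - 1) / 10
  for (m in c("standard", "baseline", "modified")) {
    bw <- if (m == "baseline") c(0, 20) else NULL
    z1 <- zscore(time_series(t, x, 10), m, bw)$values
    z2 <- zscore(time_series(t, 3.7 * x + 11, 10), m, bw)$values
    expect_equal(z2, z1, tolerance = 1e-10)
  }
})

test_that("dF/F recovers injected activity better than the raw signal", {
  p <- synth_params(duration = 300, rate = 20,
                    artifact_events = list(c(50, 60, 2), c(150, -40, 3),
                                           c(250, 50, 1.5)),
                    transient_times = seq(20, 280, by = 20) + 0.5,
                    noise_sd = 1.5, seed = 77)
  gen <- generate_session(p)
  ses <- gen$session
  dff <- compute_dff_chunked(as_chunked(ses))
  r_dff <- cor(dff$values, gen$truth$clean_activity)
  r_raw <- cor(ses$signal$values, gen$truth$clean_activity)
  expect_gt(r_dff, r_raw)
})
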