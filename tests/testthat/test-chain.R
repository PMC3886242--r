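test_that("EMA constants follow from the smoothing factor", {
  expect_equal(ema_time_constant(0.98), 49, tolerance = 1e-12)
  expect_equal(signif(ema_cutoff_hz(0.98, tr = 1), 1), 0.003)
})

test_that("EMA residual is zero on constant input and decays after a step", {
  st <- fsvps:::ema_init(0.98)
  outs <- numeric(10)
  for (i in 1:10) {
    r <- ema_step(st, 5)
    st <- r$state
    outs[i] <- r$value
  }
  expect_equal(outs, rep(0, 10), tolerance = 1e-15)

  # step from 5 to 7: residual alpha^k * step
  resid <- numeric(6)
  for (i in 1:6) {
    r <- ema_step(st, 7)
    st <- r$state
    resid[i] <- r$value
  }
  expect_equal(resid, 0.98^(1:6) * 2, tolerance = 1e-12)

  # alpha = 0: the average tracks the input exactly, residual always 0
  st0 <- fsvps:::ema_init(0)
  for (y in c(3, -1, 10)) {
    r <- ema_step(st0, y)
    st0 <- r$state
    expect_equal(r$value, 0)
  }
  expect_error(ema_step(st0, NaN), class = "svps_data_error")
})

test_that("EMA residual amplitude matches the one-pole transfer function", {
  alpha <- 0.98
  f <- 0.05
  n <- 3000
  t <- seq_len(n)
  y <- sin(2 * pi * f * t)
  st <- fsvps:::ema_init(alpha)
  out <- numeric(n)
  for (i in t) {
    r <- ema_step(st, y[i])
    st <- r$state
    out[i] <- r$value
  }
  tail_idx <- (n - 999):n
  fit <- lm(out[tail_idx] ~ sin(2 * pi * f * t[tail_idx]) +
              cos(2 * pi * f * t[tail_idx]) - 1)
  measured <- sqrt(sum(coef(fit)^2))
  expect_equal(measured, ema_residual_gain(alpha, f, tr = 1),
               tolerance = 0.02)
})

test_that("running SD matches closed forms and the two-pass formula", {
  tr <- fsvps:::welford_init()
  for (y in c(1, 1, 1)) {
    r <- update_running_std(tr, y)
    tr <- r$tracker
  }
  expect_equal(r$sd, 0)

  tr <- fsvps:::welford_init()
  r <- update_running_std(tr, 0)
  expect_equal(r$sd, 0)  # single sample: gate disabled
  r <- update_running_std(r$tracker, 2)
  expect_equal(r$sd, sqrt(2), tolerance = 1e-14)

  set.seed(8)
  x <- rnorm(1e4, mean = 3, sd = 2.5)
  tr <- fsvps:::welford_init()
  for (y in x) {
    r <- update_running_std(tr, y)
    tr <- r$tracker
  }
  expect_lt(abs(r$sd - twopass_sd(x)) / twopass_sd(x), 1e-10)
})

test_that("Kalman filter converges monotonically on constant input", {
  st <- fsvps:::kalman_init(4, 0.9)
  r <- kalman_step(st, 0)  # initialise at 0
  st <- r$state
  vals <- numeric(30)
  for (i in 1:30) {
    r <- kalman_step(st, 1, th_sp = Inf)
    st <- r$state
    vals[i] <- r$value
  }
  expect_true(all(diff(c(0, vals)) >= -1e-14))
  expect_true(all(vals <= 1 + 1e-12))
  expect_gt(vals[30], 0.9)
  expect_error(kalman_step(st, Inf), class = "svps_data_error")
})

test_that("Kalman gate vetoes an outlier and coasts on the prediction", {
  set.seed(77)
  st <- fsvps:::kalman_init(4, 0.9, spike_warmup = 20)
  tr <- fsvps:::welford_init()
  for (y in rnorm(100)) {
    up <- update_running_std(tr, y)
    tr <- up$tracker
    r <- kalman_step(st, y, th_sp = 0.9 * up$sd, gate_n = tr$n)
    st <- r$state
  }
  x_before <- st$x_est
  up <- update_running_std(tr, 100)
  r <- kalman_step(st, 100, th_sp = 0.9 * up$sd, gate_n = up$tracker$n)
  expect_true(r$spike)
  expect_identical(r$value, x_before)
  expect_identical(r$state$x_est, x_before)
})

test_that("Kalman output suppresses high frequencies on white noise", {
  set.seed(5)
  n <- 1e4
  y <- rnorm(n)
  st <- fsvps:::kalman_init(4, 0.9)
  out <- numeric(n)
  for (i in seq_len(n)) {
    r <- kalman_step(st, y[i], th_sp = Inf)
    st <- r$state
    out[i] <- r$value
  }
  pw <- Mod(stats::fft(out - mean(out)))^2 / n
  freqs <- (seq_len(n) - 1) / n
  p_low <- mean(pw[freqs >= 0.005 & freqs <= 0.015])
  p_high <- mean(pw[freqs >= 0.19 & freqs <= 0.21])
  expect_lt(p_high, p_low)
  expect_lt(p_high / p_low, 0.25)
})

test_that("normalisation maps into [0,1] with a non-shrinking range", {
  st <- fsvps:::norm_init(floor_range = 0.5)
  r <- normalize_step(st, 3)
  expect_equal(r$value, 0)  # first sample convention
  st <- r$state
  r <- normalize_step(st, 3.25)
  expect_equal(r$value, 0.5)  # floor range still active: 0.25 / 0.5
  st <- r$state
  r <- normalize_step(st, 5)  # range widens to 2
  expect_equal(r$value, 1)
  st <- r$state
  r <- normalize_step(st, 4)
  expect_equal(r$value, 0.5)
  st <- r$state
  # late shrink in spread does not shrink the range
  r <- normalize_step(st, 3.5)
  expect_equal(r$value, 0.25)

  set.seed(6)
  vals <- process_series(cumsum(rnorm(200)), svps_chain())$feedback
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("streaming steps equal batch replay", {
  set.seed(31)
  y <- 0.08 + cumsum(rnorm(150, sd = 1e-4))
  cfg <- svps_chain()
  batch <- process_series(y, cfg)
  st <- chain_init(cfg, floor_ref = y[1])
  rows <- vector("list", length(y))
  for (i in seq_along(y)) {
    r <- chain_step(st, y[i])
    st <- r$state
    rows[[i]] <- r$out
  }
  expect_identical(dplyr::bind_rows(rows), batch)
})

test_that("the conditioning order detrend -> despike -> normalise matters", {
  set.seed(41)
  n <- 200
  drift <- seq(0, 5, length.out = n)
  y <- drift + rnorm(n, sd = 0.2)
  cfg <- svps_chain()
  standard <- process_series(y, cfg)

  # permuted order: Kalman first, then EMA, then normalise
  kal <- fsvps:::kalman_init(cfg$lambda_ratio, cfg$thsp_coeff,
                             cfg$spike_warmup)
  ema <- fsvps:::ema_init(cfg$alpha)
  nrm <- fsvps:::norm_init(cfg$floor_fraction * y[1])
  tr <- fsvps:::welford_init()
  permuted <- numeric(n)
  for (i in seq_len(n)) {
    up <- update_running_std(tr, y[i])
    tr <- up$tracker
    k <- kalman_step(kal, y[i], th_sp = 0.9 * up$sd, gate_n = tr$n)
    kal <- k$state
    e <- ema_step(ema, k$value)
    ema <- e$state
    nm <- normalize_step(nrm, e$value)
    nrm <- nm$state
    permuted[i] <- nm$value
  }
  expect_gt(max(abs(permuted - standard$feedback)), 0.01)
})
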