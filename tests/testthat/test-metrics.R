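test_that("CNR matches its closed form and is scale invariant", {
  a <- sqrt(0.5)
  series <- c(1 - a, 1, 1 + a, 2 - a, 2, 2 + a)
  labels <- rep(c("baseline", "activation"), each = 3)
  # means 1 and 2, variances 0.5 each -> CNR = 1 / sqrt(1) = 1
  expect_equal(cnr(series, labels), 1, tolerance = 1e-12)
  expect_equal(cnr(3.7 * series, labels), 1, tolerance = 1e-12)
  expect_equal(cnr(series + 10, labels), 1, tolerance = 1e-12)

  flat <- c(1, 1.4, 0.6, 1 - a, 1, 1 + a)
  expect_equal(cnr(c(flat[1:3], flat[1:3] + 0), rep(c("baseline", "activation"),
                                                    each = 3)), 0)
  expect_error(cnr(rep(1, 6), labels), class = "svps_numeric_error")
  expect_error(cnr(c(1, 2), c("baseline", "activation")),
               class = "svps_data_error")
})

test_that("percent change matches its closed form", {
  series <- c(0.98, 1.00, 1.02, 1.03, 1.05, 1.07)
  labels <- rep(c("baseline", "activation"), each = 3)
  expect_equal(percent_change(series, labels), 0.05, tolerance = 1e-12)
  expect_equal(percent_change(2.4 * series, labels), 0.05, tolerance = 1e-12)
  expect_equal(percent_change(c(1, 2, 3, 1, 2, 3), labels), 0)
  expect_error(percent_change(c(-1, 0, 1, 1, 2, 3), labels),
               class = "svps_numeric_error")
})

test_that("metrics accept data frames with value/label columns", {
  df <- tibble::tibble(t2star = c(1, 1.1, 0.9, 2, 2.1, 1.9),
                       label = rep(c("baseline", "activation"), each = 3))
  expect_equal(cnr(df), cnr(df$t2star, df$label))
  expect_equal(percent_change(df), percent_change(df$t2star, df$label))
})

test_that("block GLM equals a normal-equations oracle", {
  des <- svps_design(block_len = 10, n_blocks = 3, n_discard = 0)
  set.seed(17)
  for (i in 1:50) {
    y <- rnorm(des$n_reps) + 0.3 * (des$labels == "activation")
    expect_equal(block_glm_tvalue(y, des$labels),
                 ols_tvalue_oracle(y, des$labels), tolerance = 1e-8)
  }
})

test_that("block GLM t is invariant to constant shifts and flags degeneracy", {
  des <- svps_design(block_len = 5, n_blocks = 2, n_discard = 0)
  set.seed(3)
  y <- rnorm(des$n_reps)
  expect_equal(block_glm_tvalue(y, des$labels),
               block_glm_tvalue(y + 123.4, des$labels), tolerance = 1e-8)

  boxcar <- as.numeric(des$labels == "activation")
  g <- block_glm(boxcar, des$labels)
  expect_true(g$infinite)
  expect_identical(g$t_value, Inf)
  expect_true(is.infinite(glance(g)$t_value))
})

test_that("HRF convolution changes the regressor but keeps the interface", {
  des <- svps_design(block_len = 10, n_blocks = 3, n_discard = 0)
  set.seed(9)
  y <- rnorm(des$n_reps) + 0.5 * (des$labels == "activation")
  t_plain <- block_glm_tvalue(y, des$labels)
  t_hrf <- block_glm_tvalue(y, des$labels, hrf = TRUE)
  expect_true(is.finite(t_hrf))
  expect_false(identical(t_plain, t_hrf))
})

test_that("event averages reduce identical cycles exactly", {
  des <- svps_design(block_len = 3, n_blocks = 4, n_discard = 0)
  cycle <- c(1, 2, 3, 6, 5, 4)
  series <- rep(cycle, 4)
  ev <- event_average(series, des, value = NULL)
  expect_equal(ev$cycle_mean, cycle)
  expect_equal(ev$cycle_sd, rep(0, 6))
  expect_identical(attr(ev, "n_cycles"), 4L)

  # two cycles offset by d: positionwise SD is d / sqrt(2)
  des2 <- svps_design(block_len = 3, n_blocks = 2, n_discard = 0)
  d <- 0.8
  ev2 <- event_average(c(cycle, cycle + d), des2)
  expect_equal(ev2$cycle_sd, rep(d / sqrt(2), 6), tolerance = 1e-12)
  expect_equal(ev2$cycle_mean, cycle + d / 2, tolerance = 1e-12)

  expect_error(event_average(cycle, des2), class = "svps_data_error")
})

test_that("event averages equal a brute-force loop on random series", {
  des <- svps_design(block_len = 4, n_blocks = 3, n_discard = 2)
  set.seed(14)
  series <- rnorm(des$n_reps)
  ev <- event_average(series, des)
  oracle <- event_average_oracle(series, des)
  expect_equal(ev$cycle_mean, oracle$mean, tolerance = 1e-12)
  expect_equal(ev$cycle_sd, oracle$sd, tolerance = 1e-12)
  expect_identical(attr(ev, "n_cycles"), oracle$n_cycles)
})

test_that("event SNR follows its definition and scales with variability", {
  des <- svps_design(block_len = 2, n_blocks = 2, n_discard = 0)
  ev <- event_average(c(0, 2, 4, 0, 0, 2, 4, 0), des)
  ev$cycle_sd <- rep(1, 4)
  expect_equal(event_snr(ev), 4)
  ev$cycle_sd <- rep(2, 4)
  expect_equal(event_snr(ev), 2)

  # halving cycle-to-cycle variability doubles SNR at equal amplitude
  des6 <- svps_design(block_len = 5, n_blocks = 6, n_discard = 0)
  template <- 2 * sin(2 * pi * (seq_len(10) - 1) / 10)
  set.seed(25)
  ratio <- replicate(60, {
    make_arm <- function(sigma) {
      series <- as.vector(vapply(1:6, function(k) {
        template + rnorm(10, sd = sigma)
      }, numeric(10)))
      event_snr(event_average(series, des6))
    }
    make_arm(0.25) / make_arm(0.5)
  })
  expect_equal(mean(ratio), 2, tolerance = 0.12)
})

test_that("session metrics agree with definitional loops on the raw series", {
  ses <- simulate_session(seed = 12)
  fb <- process_session(ses)
  m <- session_metrics(fb, ses$design)
  ret <- dplyr::filter(tibble::as_tibble(fb), !discarded)

  cond <- ret$filtered
  st_cond <- split(cond, ret$label)
  expect_equal(m$cnr,
               (mean(st_cond$activation) - mean(st_cond$baseline)) /
                 sqrt(var(st_cond$activation) + var(st_cond$baseline)),
               tolerance = 1e-12)

  raw <- ret$t2star_raw[!(ret$spike %in% TRUE)]
  lab <- ret$label[!(ret$spike %in% TRUE)]
  st_raw <- split(raw, lab)
  expect_equal(m$percent,
               (mean(st_raw$activation) - mean(st_raw$baseline)) /
                 mean(st_raw$baseline), tolerance = 1e-12)
  expect_true(is.finite(m$t_value))
  expect_identical(m$dof, length(cond) - 2L)
})
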