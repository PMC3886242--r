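test_that("generate_fid matches the closed-form decay model", {
  acq <- tiny_acq()
  fid <- generate_fid(single_component(t2star = 0.05), acq)
  # |A e^{-t/T2}| at t = T2 is e^-1
  expect_equal(Mod(fid$samples[51]), exp(-1), tolerance = 1e-12)
  expect_equal(Mod(fid$samples[1]), 1, tolerance = 1e-12)

  two <- svps_components(amplitude = c(1, 0.5), frequency = c(0, 125),
                         phase = c(0.4, -1.1), t2star = c(0.05, 0.02))
  fid2 <- generate_fid(two, acq)
  expect_equal(Mod(fid2$samples[1]),
               Mod(1 * exp(0.4i) + 0.5 * exp(-1.1i)), tolerance = 1e-12)

  # linearity: a two-component frame is the sum of its single-component frames
  f_a <- generate_fid(svps_components(1, 0, 0.4, 0.05), acq)
  f_b <- generate_fid(svps_components(0.5, 125, -1.1, 0.02), acq)
  expect_equal(fid2$samples, f_a$samples + f_b$samples, tolerance = 1e-14)
})

test_that("generate_fid validates parameters", {
  expect_error(svps_components(1, 0, 0, -0.1), class = "svps_config_error")
  expect_error(svps_acquisition(bandwidth = -1), class = "svps_config_error")
  expect_error(generate_fid(single_component(frequency = 900), tiny_acq()),
               class = "svps_config_error")
})

test_that("complex noise has the nominal power", {
  sigma <- 0.5
  set.seed(42)
  fid <- generate_fid(single_component(amplitude = 0),
                      svps_acquisition(n_points = 1e5), noise_sd = sigma)
  # E|z|^2 = 2 sigma^2 for independent quadratures
  expect_equal(mean(Mod(fid$samples)^2), 2 * sigma^2, tolerance = 0.03)
})

test_that("session generation is deterministic and bookkeeps labels", {
  des <- tiny_design()
  s1 <- simulate_session(design = des, acq = tiny_acq(), seed = 7)
  s2 <- simulate_session(design = des, acq = tiny_acq(), seed = 7)
  expect_identical(s1$fids, s2$fids)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_session(design = des, acq = tiny_acq(), seed = 8)
  expect_false(identical(s1$fids, s3$fids))

  expect_identical(s1$truth$label, des$labels)
  expect_identical(des$labels[1:des$block_len],
                   rep("baseline", des$block_len))
  expect_identical(des$labels[(des$block_len + 1):(2 * des$block_len)],
                   rep("activation", des$block_len))
})

test_that("zero-contrast noiseless sessions produce identical frames", {
  ses <- simulate_session(design = tiny_design(),
                          bold = svps_bold(activation_delta = 0),
                          acq = tiny_acq(), noise = quiet_noise(), seed = 1)
  ref <- ses$fids[, 1]
  for (i in 2:ncol(ses$fids)) expect_identical(ses$fids[, i], ref)
})

test_that("instant transitions give an exact two-valued boxcar", {
  b <- svps_bold(activation_delta = 0.05, transition_tau = 0)
  ses <- simulate_session(design = tiny_design(), bold = b,
                          acq = tiny_acq(), noise = quiet_noise(), seed = 1)
  expected <- ifelse(ses$truth$label == "activation",
                     b$baseline_t2star * 1.05, b$baseline_t2star)
  expect_equal(ses$truth$true_t2star, expected, tolerance = 1e-14)
  expect_equal(max(ses$truth$true_t2star) / min(ses$truth$true_t2star) - 1,
               0.05, tolerance = 1e-12)
})

test_that("first-order transitions follow the recursive response", {
  des <- tiny_design()
  b <- svps_bold(transition_tau = 3)
  ses <- simulate_session(design = des, bold = b, acq = tiny_acq(),
                          noise = quiet_noise(), seed = 1)
  a <- exp(-des$tr / b$transition_tau)
  state <- b$baseline_t2star
  for (i in seq_len(des$n_reps)) {
    target <- if (des$labels[i] == "activation") {
      b$baseline_t2star * 1.05
    } else {
      b$baseline_t2star
    }
    state <- target + (state - target) * a
    expect_equal(ses$truth$true_t2star[i], state, tolerance = 1e-14)
  }
})

test_that("spike counts follow the binomial expectation", {
  des <- svps_design(n_discard = 0)
  counts <- vapply(1:200, function(seed) {
    ses <- simulate_session(design = des, acq = tiny_acq(n_points = 16),
                            noise = quiet_noise(spike_prob = 0.02), seed = seed)
    sum(ses$truth$spike)
  }, numeric(1))
  expected <- des$n_reps * 0.02
  se_mean <- sqrt(des$n_reps * 0.02 * 0.98 / 200)
  expect_lt(abs(mean(counts) - expected), 1.96 * se_mean)
})

test_that("spikes and drift are recorded in the ground truth", {
  ses <- simulate_session(design = tiny_design(),
                          acq = tiny_acq(),
                          noise = quiet_noise(spike_prob = 0.5,
                                              spike_scale = 8,
                                              drift_amplitude = 0.002),
                          seed = 5)
  tr <- ses$truth
  expect_gt(sum(tr$spike), 0)
  on_spike <- tr$realized_t2star - tr$true_t2star - tr$drift
  expect_true(all(on_spike[tr$spike] > 0))
  expect_true(all(abs(on_spike[!tr$spike]) < 1e-12))
  expect_equal(max(abs(tr$drift)), 0.002, tolerance = 0.05)
})
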