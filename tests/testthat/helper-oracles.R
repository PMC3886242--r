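# small fixtures ------------------------------------------------------------

tiny_acq <- function(n_points = 64, bandwidth = 1000, te = 0.02) {
  svps_acquisition(bandwidth = bandwidth, n_points = n_points, te = te)
}

tiny_design <- function(block_len = 5, n_blocks = 2, n_discard = 2, tr = 1) {
  svps_design(tr = tr, block_len = block_len, n_blocks = n_blocks,
              n_discard = n_discard)
}

quiet_noise <- function(complex_noise_sd = 0, drift_amplitude = 0,
                        spike_prob = 0, b0_wander_sd = 0, ...) {
  svps_noise(complex_noise_sd = complex_noise_sd,
             drift_amplitude = drift_amplitude,
             spike_prob = spike_prob, b0_wander_sd = b0_wander_sd, ...)
}

single_component <- function(t2star = 0.05, amplitude = 1, frequency = 0,
                             phase = 0) {
  svps_components(amplitude = amplitude, frequency = frequency,
                  phase = phase, t2star = t2star)
}

# independent oracles --------------------------------------------------------

# batch two-pass sample SD
twopass_sd <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

# normal-equations OLS t-value for y ~ 1 + boxcar
ols_tvalue_oracle <- function(y, labels) {
  x <- as.numeric(labels == "activation")
  X <- cbind(1, x)
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% (t(X) %*% y)
  res <- y - X %*% beta
  s2 <- sum(res^2) / (length(y) - 2)
  beta[2] / sqrt(s2 * xtx_inv[2, 2])
}

# dense zero-padded DFT argmax (sub-bin peak reference)
dense_peak_oracle <- function(samples, bandwidth, pad = 16) {
  n <- length(samples)
  big <- stats::fft(c(samples, rep(0 + 0i, (pad - 1) * n)))
  k <- which.max(Mod(big)) - 1
  if (k > pad * n / 2) k <- k - pad * n
  k * bandwidth / (pad * n)
}

# two-parameter exponential least squares |A e^{-t/T2}| on magnitudes
expfit_oracle <- function(t, mag, start = c(1, 0.05)) {
  obj <- function(p) sum((mag - p[1] * exp(-t / p[2]))^2)
  stats::optim(start, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))$par[2]
}

# brute-force regression-length scan: per-frame loglinear_t2 loop
bruteforce_lcurve <- function(session, candidate_lengths, config) {
  design <- session$design
  retain <- seq.int(design$n_discard + 1L, design$n_reps)
  t_vals <- rep(NA_real_, length(candidate_lengths))
  conditioned <- lapply(seq_len(design$n_reps), function(i) {
    condition_frame(fsvps:::session_frame(session, i), config)$frame
  })
  for (ci in seq_along(candidate_lengths)) {
    t2 <- rep(NA_real_, design$n_reps)
    for (i in seq_len(design$n_reps)) {
      fit <- tryCatch(loglinear_t2(conditioned[[i]], candidate_lengths[ci],
                                   min_fit_points = config$min_fit_points,
                                   t_start = config$fit_start),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$fit_ok) t2[i] <- fit$t2star
    }
    if (all(is.na(t2))) next
    last <- NA_real_
    for (i in seq_along(t2)) {
      if (is.na(t2[i])) t2[i] <- last else last <- t2[i]
    }
    first_ok <- which(!is.na(t2))[1]
    if (first_ok > 1) t2[seq_len(first_ok - 1)] <- t2[first_ok]
    t_vals[ci] <- tryCatch(block_glm_tvalue(t2[retain], design$labels[retain]),
                           error = function(e) NA_real_)
  }
  best <- which(t_vals == max(t_vals, na.rm = TRUE))
  best <- best[which.min(candidate_lengths[best])]
  list(l_optim = candidate_lengths[best], t_curve = t_vals)
}

# per-position event-average loop
event_average_oracle <- function(series, design) {
  cycle_len <- 2L * design$block_len
  usable <- !is.na(series) & seq_len(design$n_reps) > design$n_discard
  cyc <- (seq_len(design$n_reps) - 1L) %/% cycle_len + 1L
  keep <- Filter(function(k) all(usable[cyc == k]), unique(cyc))
  means <- sds <- numeric(cycle_len)
  for (p in seq_len(cycle_len)) {
    vals <- vapply(keep, function(k) series[which(cyc == k)[p]], numeric(1))
    means[p] <- mean(vals)
    sds[p] <- stats::sd(vals)
  }
  list(mean = means, sd = sds, n_cycles = length(keep))
}
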