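#' Real-time chain configuration
#'
#' Parameters of the streaming conditioning chain applied to the
#' per-repetition T2* samples: EMA drift removal, spike-gated scalar Kalman
#' low-pass, and incremental range normalisation.
#'
#' @param alpha EMA smoothing factor (default 0.98). At TR = 1 s this gives
#'   a filter time constant `alpha / (1 - alpha) = 49` samples and a -3 dB
#'   high-pass cutoff of about 0.003 Hz, below the 0.01-0.12 Hz BOLD band.
#' @param lambda_ratio Kalman update ratio lambda (default 4), keeping the
#'   low-pass cutoff near `1 / (pi * lambda)` of the sampling rate. The
#'   observation noise `r` is tracked from the running variance of the
#'   filter input and the process noise is `q = r / lambda^2`.
#' @param thsp_coeff Spike-threshold coefficient (default 0.9): an update is
#'   vetoed when `|K (y - x_pred)|` exceeds `thsp_coeff` times the running
#'   SD of the configured source series.
#' @param floor_fraction Normalisation floor as a fraction of the first
#'   valid baseline T2* (default 0.01, the expected 1 percent BOLD effect).
#' @param spike_source Which series feeds the spike-threshold SD tracker:
#'   `"raw"` (default, the raw T2* samples entering the chain) or
#'   `"detrended"` (the EMA residual entering the Kalman filter).
#' @param spike_warmup Number of tracker samples required before the spike
#'   gate arms (default 20; below that an SD estimate is too unstable to
#'   set a rejection threshold).
#' @return A list with class `svps_chain`.
#' @export
svps_chain <- function(alpha = 0.98, lambda_ratio = 4, thsp_coeff = 0.9,
                       floor_fraction = 0.01, spike_source = c("raw", "detrended"),
                       spike_warmup = 20) {
  check_number(alpha, "alpha", lower = 0, upper = 1 - .Machine$double.eps)
  check_number(lambda_ratio, "lambda_ratio", lower = .Machine$double.eps)
  check_number(thsp_coeff, "thsp_coeff", lower = 0)
  check_number(floor_fraction, "floor_fraction", lower = 0)
  check_number(spike_warmup, "spike_warmup", lower = 2)
  spike_source <- match.arg(spike_source)
  structure(list(alpha = alpha, lambda_ratio = lambda_ratio,
                 thsp_coeff = thsp_coeff, floor_fraction = floor_fraction,
                 spike_source = spike_source,
                 spike_warmup = as.integer(spike_warmup)),
            class = "svps_chain")
}

#' EMA filter constants
#'
#' For smoothing factor `alpha` the exponential moving average has time
#' constant `tau = alpha / (1 - alpha)` samples; its residual (the
#' detrended signal) is a high-pass with -3 dB cutoff near
#' `1 / (2 pi tau)` cycles per sample, i.e. `1 / (2 pi tau TR)` Hz.
#'
#' @param alpha Smoothing factor in `[0, 1)`.
#' @param tr Sampling interval in seconds.
#' @return `ema_time_constant()`: tau in samples. `ema_cutoff_hz()`: cutoff
#'   in Hz.
#' @examples
#' ema_time_constant(0.98)   # 49 samples
#' ema_cutoff_hz(0.98, 1)    # ~0.003 Hz
#' @export
ema_time_constant <- function(alpha) {
  check_number(alpha, "alpha", lower = 0, upper = 1 - .Machine$double.eps)
  alpha / (1 - alpha)
}

#' @rdname ema_time_constant
#' @export
ema_cutoff_hz <- function(alpha, tr = 1) {
  check_number(tr, "tr", lower = .Machine$double.eps)
  1 / (2 * pi * ema_time_constant(alpha) * tr)
}

#' @rdname ema_time_constant
#' @param f Frequency in Hz at which to evaluate the residual gain.
#' @details `ema_residual_gain()` is the closed-form amplitude response of
#'   the detrending residual `y - EMA(y)`: with
#'   `H(z) = (1 - alpha) / (1 - alpha z^-1)` the residual gain at frequency
#'   `f` is `|1 - H(e^{i 2 pi f TR})|`.
#' @export
ema_residual_gain <- function(alpha, f, tr = 1) {
  w <- 2 * pi * f * tr
  h <- (1 - alpha) / (1 - alpha * exp(-1i * w))
  Mod(1 - h)
}

## --- EMA ---------------------------------------------------------------

ema_init <- function(alpha) {
  list(alpha = alpha, current_avg = NA_real_, initialized = FALSE)
}

#' One EMA detrending step
#'
#' Updates the exponential moving average
#' `avg <- alpha * avg + (1 - alpha) * y` (the first call initialises
#' `avg = y`) and returns the residual `y - avg`, the drift-free signal.
#'
#' @param state An EMA state (`fsvps:::ema_init(alpha)` or from a previous
#'   step).
#' @param y New sample (finite).
#' @return A list: `state` (updated), `value` (detrended sample).
#' @export
ema_step <- function(state, y) {
  if (!is.finite(y)) svps_abort("non-finite EMA input",
                                class = "svps_data_error")
  if (!state$initialized) {
    state$current_avg <- y
    state$initialized <- TRUE
  } else {
    state$current_avg <- state$alpha * state$current_avg +
      (1 - state$alpha) * y
  }
  list(state = state, value = y - state$current_avg)
}

## --- running (Welford) SD ----------------------------------------------

welford_init <- function() list(n = 0L, mean = 0, m2 = 0)

#' Incrementally updated standard deviation
#'
#' Single-pass, numerically stable (Welford) update of the running sample
#' standard deviation (n - 1 denominator). With fewer than two samples the
#' SD is reported as 0, and consumers treat the value as not yet defined.
#'
#' @param tracker A tracker (`fsvps:::welford_init()` or from a previous
#'   step).
#' @param y New sample.
#' @return A list: `tracker` (updated), `sd` (running SD so far).
#' @export
update_running_std <- function(tracker, y) {
  if (!is.finite(y)) svps_abort("non-finite input to SD tracker",
                                class = "svps_data_error")
  tracker$n <- tracker$n + 1L
  delta <- y - tracker$mean
  tracker$mean <- tracker$mean + delta / tracker$n
  tracker$m2 <- tracker$m2 + delta * (y - tracker$mean)
  sd_val <- if (tracker$n >= 2L) sqrt(tracker$m2 / (tracker$n - 1L)) else 0
  list(tracker = tracker, sd = sd_val)
}

## --- spike-gated Kalman -------------------------------------------------

kalman_init <- function(lambda_ratio, thsp_coeff, spike_warmup = 2L) {
  list(x_est = NA_real_, p_cov = 0, lambda = lambda_ratio,
       thsp_coeff = thsp_coeff, spike_warmup = as.integer(spike_warmup),
       input_stats = welford_init(), initialized = FALSE)
}

#' One spike-gated Kalman step
#'
#' Scalar random-walk Kalman filter used as an adaptive low-pass: predict
#' `x_pred = x_est`, `p_pred = p_cov + q`; gain `K = p_pred / (p_pred + r)`
#' (observation matrix H = 1). The observation noise `r` tracks the running
#' variance of the filter input and `q = r / lambda^2`, which places the
#' effective low-pass cutoff near `1 / (pi * lambda)` of the sampling rate.
#' Only accepted samples feed the `r` tracker — the current sample is
#' ingested after the gate and vetoed samples never are, so an outlier
#' cannot inflate the assumed observation noise (and deflate the gain) at
#' the very step on which it must be detected.
#'
#' Spike gate: when the magnitude of the update term `K (y - x_pred)`
#' exceeds the threshold `Th_sp = thsp_coeff * running SD` (supplied by the
#' caller from the configured source series), the measurement update is
#' vetoed — the filter coasts on its prediction (`x_est <- x_pred`,
#' `p_cov <- p_pred`) and the sample is flagged as a spike. The gate is
#' inactive while the SD tracker holds fewer than `spike_warmup` samples
#' (`gate_n`), or when `th_sp` is not finite.
#'
#' @param state A Kalman state (`fsvps:::kalman_init()` or from a previous
#'   step).
#' @param y New (typically detrended) sample.
#' @param th_sp Current spike threshold; `Inf` disables the gate.
#' @param gate_n Number of samples behind the threshold estimate.
#' @return A list: `state` (updated), `value` (filtered sample), `spike`
#'   (flag).
#' @export
kalman_step <- function(state, y, th_sp = Inf, gate_n = Inf) {
  if (!is.finite(y)) svps_abort("non-finite Kalman input",
                                class = "svps_data_error")
  prev_sd <- if (state$input_stats$n >= 2L) {
    sqrt(state$input_stats$m2 / (state$input_stats$n - 1L))
  } else {
    0
  }
  r <- max(prev_sd^2, .Machine$double.xmin)
  q <- r / state$lambda^2

  if (!state$initialized) {
    state$input_stats <- update_running_std(state$input_stats, y)$tracker
    state$x_est <- y
    state$p_cov <- 0
    state$initialized <- TRUE
    return(list(state = state, value = y, spike = FALSE))
  }

  x_pred <- state$x_est
  p_pred <- state$p_cov + q
  k_gain <- p_pred / (p_pred + r)
  update <- k_gain * (y - x_pred)

  gate_on <- is.finite(th_sp) && gate_n >= state$spike_warmup
  if (gate_on && abs(update) > th_sp) {
    state$x_est <- x_pred
    state$p_cov <- p_pred
    return(list(state = state, value = x_pred, spike = TRUE))
  }
  # robust-variance guard: a >5 sigma innovation never informs the noise
  # estimate, even before the spike gate arms — otherwise an early outlier
  # inflates r and masks later spikes
  wild <- state$input_stats$n >= 5L && prev_sd > 0 &&
    abs(y - x_pred) > 5 * prev_sd
  if (!wild) {
    state$input_stats <- update_running_std(state$input_stats, y)$tracker
  }
  state$x_est <- x_pred + update
  state$p_cov <- (1 - k_gain) * p_pred
  list(state = state, value = state$x_est, spike = FALSE)
}

## --- range normalisation ------------------------------------------------

norm_init <- function(floor_range) {
  list(obs_min = NA_real_, obs_max = NA_real_,
       floor_range = floor_range, initialized = FALSE)
}

#' One normalisation step
#'
#' Maps the filtered sample into the display range `[0, 1]` using the
#' incrementally updated session minimum and maximum. The effective range
#' is `max(obs_max - obs_min, floor_range)` where `floor_range` encodes the
#' expected 1 percent BOLD effect; once widened, the range never shrinks
#' within a session. The first sample maps to 0 by convention.
#'
#' @param state A normaliser state (`fsvps:::norm_init(floor_range)` or from
#'   a previous step).
#' @param y Filtered sample.
#' @return A list: `state` (updated), `value` (display fraction in
#'   `[0, 1]`).
#' @export
normalize_step <- function(state, y) {
  if (!is.finite(y)) svps_abort("non-finite normaliser input",
                                class = "svps_data_error")
  if (!state$initialized) {
    state$obs_min <- y
    state$obs_max <- y
    state$initialized <- TRUE
  } else {
    state$obs_min <- min(state$obs_min, y)
    state$obs_max <- max(state$obs_max, y)
  }
  range_eff <- max(state$obs_max - state$obs_min, state$floor_range)
  value <- if (range_eff <= 0) 0 else (y - state$obs_min) / range_eff
  list(state = state, value = max(min(value, 1), 0))
}

## --- whole chain ---------------------------------------------------------

#' Initialise the streaming chain
#'
#' @param config An [svps_chain] configuration.
#' @param floor_ref Reference level for the normalisation floor, typically
#'   the first valid baseline T2* estimate; the floor is
#'   `floor_fraction * floor_ref`.
#' @return An opaque chain state for [chain_step()].
#' @export
chain_init <- function(config = svps_chain(), floor_ref = 0) {
  stopifnot(inherits(config, "svps_chain"))
  list(config = config,
       ema = ema_init(config$alpha),
       raw_stats = welford_init(),
       det_stats = welford_init(),
       kalman = kalman_init(config$lambda_ratio, config$thsp_coeff,
                            config$spike_warmup),
       norm = norm_init(config$floor_fraction * floor_ref))
}

#' Advance the streaming chain by one sample
#'
#' Applies the fixed conditioning order — EMA detrend, spike-gated Kalman,
#' range normalisation — to one raw T2* sample and updates every piece of
#' streaming state exactly once.
#'
#' @param state A chain state from [chain_init()] or a previous step.
#' @param y Raw T2* sample (seconds).
#' @return A list: `state`, and `out`, a one-row tibble with `raw`,
#'   `detrended`, `filtered`, `spike`, `feedback`.
#' @export
chain_step <- function(state, y) {
  cfg <- state$config

  up_raw <- update_running_std(state$raw_stats, y)
  state$raw_stats <- up_raw$tracker

  ema <- ema_step(state$ema, y)
  state$ema <- ema$state
  d <- ema$value

  up_det <- update_running_std(state$det_stats, d)
  state$det_stats <- up_det$tracker

  src <- if (cfg$spike_source == "raw") up_raw else up_det
  th_sp <- if (src$tracker$n >= 2L) cfg$thsp_coeff * src$sd else Inf
  gate_n <- src$tracker$n

  kal <- kalman_step(state$kalman, d, th_sp = th_sp, gate_n = gate_n)
  state$kalman <- kal$state

  nm <- normalize_step(state$norm, kal$value)
  state$norm <- nm$state

  list(state = state,
       out = tibble(raw = y, detrended = d, filtered = kal$value,
                    spike = kal$spike, feedback = nm$value))
}

#' Run the chain over a stored series
#'
#' Batch replay of [chain_step()] over a numeric vector; feeding the same
#' series sample-by-sample yields identical output.
#'
#' @param y Numeric vector of raw T2* samples.
#' @param config An [svps_chain].
#' @param floor_ref Normalisation floor reference; defaults to the first
#'   sample.
#' @return A tibble with one row per sample: `raw`, `detrended`,
#'   `filtered`, `spike`, `feedback`.
#' @export
process_series <- function(y, config = svps_chain(), floor_ref = NULL) {
  if (length(y) == 0L) return(tibble(raw = numeric(), detrended = numeric(),
                                     filtered = numeric(), spike = logical(),
                                     feedback = numeric()))
  floor_ref <- floor_ref %||% y[1]
  state <- chain_init(config, floor_ref = floor_ref)
  rows <- vector("list", length(y))
  for (i in seq_along(y)) {
    st <- chain_step(state, y[i])
    state <- st$state
    rows[[i]] <- st$out
  }
  dplyr::bind_rows(rows)
}
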