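#' Spectral component table
#'
#' Describes the exponentially decaying complex oscillators that make up a
#' simulated FID: the unsuppressed water line plus any off-resonance
#' contaminants (residual lipids, metabolites). Each row is one component
#' with amplitude `A` (arbitrary signal units), frequency `f` (Hz, relative
#' to the carrier), constant phase `phi` (radians) and apparent relaxation
#' time `t2star` (seconds).
#'
#' @param amplitude Non-negative amplitudes, one per component.
#' @param frequency Frequencies in Hz; must lie within the acquisition
#'   bandwidth (checked at generation time).
#' @param phase Phases in radians.
#' @param t2star Strictly positive apparent T2* values in seconds.
#'
#' @return A tibble with class `svps_components` and one row per component.
#' @examples
#' svps_components(amplitude = c(1, 0.1), frequency = c(0, -150),
#'                 phase = c(0.3, 1), t2star = c(0.0842, 0.03))
#' @export
svps_components <- function(amplitude, frequency, phase, t2star) {
  n <- length(amplitude)
  if (n < 1L) svps_abort("at least one component is required",
                         class = "svps_config_error")
  if (!all(lengths(list(frequency, phase, t2star)) == n)) {
    svps_abort("component fields must have equal length",
               class = "svps_config_error")
  }
  if (any(!is.finite(amplitude)) || any(amplitude < 0)) {
    svps_abort("component amplitudes must be finite and >= 0",
               class = "svps_config_error")
  }
  if (any(!is.finite(t2star)) || any(t2star <= 0)) {
    svps_abort("component t2star values must be finite and > 0",
               class = "svps_config_error")
  }
  out <- tibble(amplitude = as.numeric(amplitude),
                frequency = as.numeric(frequency),
                phase = as.numeric(phase),
                t2star = as.numeric(t2star))
  class(out) <- c("svps_components", class(out))
  out
}

#' Acquisition parameters
#'
#' Sampling parameters of one FID readout. The dwell time is
#' `1 / bandwidth`; the time axis starts at t = 0 at the first acquired
#' sample. The echo time `te` (offset of the first sample after excitation)
#' is carried as metadata only: regression lengths are reported relative to
#' the start of the acquisition window.
#'
#' @param bandwidth Acquisition bandwidth in Hz (default 1000).
#' @param n_points Number of complex samples per FID (default 512, i.e. a
#'   512 ms readout at 1 kHz, comfortably longer than any useful regression
#'   length).
#' @param te Echo time in seconds (metadata, default 0.020).
#'
#' @return A list with class `svps_acquisition`.
#' @export
svps_acquisition <- function(bandwidth = 1000, n_points = 512, te = 0.020) {
  check_number(bandwidth, "bandwidth", lower = .Machine$double.eps)
  check_number(n_points, "n_points", lower = 8)
  check_number(te, "te", lower = 0)
  structure(list(bandwidth = bandwidth, n_points = as.integer(n_points),
                 te = te),
            class = "svps_acquisition")
}

# time axis of one frame, seconds from first acquired sample
acq_time <- function(acq) {
  (seq_len(acq$n_points) - 1L) / acq$bandwidth
}

#' Block-design session layout
#'
#' Alternating baseline / activation blocks, starting with baseline. The
#' default is the standard paradigm: five 30-repetition baseline blocks
#' interleaved with five 30-repetition activation blocks at TR = 1 s
#' (300 repetitions, 5 min), with the first 10 repetitions discarded to
#' avoid T1 saturation transients.
#'
#' @param tr Repetition time in seconds.
#' @param block_len Repetitions per block.
#' @param n_blocks Number of baseline blocks (= number of activation blocks).
#' @param n_discard Leading repetitions excluded from all filter states and
#'   statistics.
#'
#' @return A list with class `svps_design`: `tr`, `n_reps`, `n_discard`,
#'   `block_len`, `n_blocks` and a per-repetition `labels` factor
#'   (`"baseline"` / `"activation"`).
#' @export
svps_design <- function(tr = 1, block_len = 30, n_blocks = 5, n_discard = 10) {
  check_number(tr, "tr", lower = .Machine$double.eps)
  check_number(block_len, "block_len", lower = 1)
  check_number(n_blocks, "n_blocks", lower = 1)
  check_number(n_discard, "n_discard", lower = 0)
  n_reps <- as.integer(2 * n_blocks * block_len)
  if (n_discard >= n_reps) {
    svps_abort("n_discard must be smaller than the number of repetitions",
               class = "svps_config_error")
  }
  block <- ceiling(seq_len(n_reps) / block_len)
  labels <- ifelse(block %% 2L == 1L, "baseline", "activation")
  structure(list(tr = tr, n_reps = n_reps, n_discard = as.integer(n_discard),
                 block_len = as.integer(block_len),
                 n_blocks = as.integer(n_blocks),
                 labels = labels),
            class = "svps_design")
}

#' @export
as_tibble.svps_design <- function(x, ...) {
  tibble(rep = seq_len(x$n_reps),
         time_s = (seq_len(x$n_reps) - 1) * x$tr,
         label = x$labels,
         discarded = seq_len(x$n_reps) <= x$n_discard)
}

# indices of repetitions retained for analysis
retained_reps <- function(design) {
  seq.int(design$n_discard + 1L, design$n_reps)
}

#' BOLD response model for the simulator
#'
#' The water T2* follows the block labels through a two-state first-order
#' system: during activation it relaxes towards
#' `baseline_t2star * (1 + activation_delta)` with time constant
#' `transition_tau`, and back towards `baseline_t2star` during baseline.
#' `transition_tau = 0` gives an ideal boxcar.
#'
#' @param baseline_t2star Baseline apparent T2* in seconds (default 0.0842,
#'   a typical unsuppressed-water value at 7 T).
#' @param activation_delta Fractional T2* change during activation
#'   (default 0.05, i.e. a 5 percent BOLD-driven increase).
#' @param transition_tau Rise/fall time constant in seconds (default 3).
#'
#' @return A list with class `svps_bold`.
#' @export
svps_bold <- function(baseline_t2star = 0.0842, activation_delta = 0.05,
                      transition_tau = 3) {
  check_number(baseline_t2star, "baseline_t2star", lower = .Machine$double.eps)
  check_number(activation_delta, "activation_delta")
  if (1 + activation_delta <= 0) {
    svps_abort("activation_delta must keep T2* positive",
               class = "svps_config_error")
  }
  check_number(transition_tau, "transition_tau", lower = 0)
  structure(list(baseline_t2star = baseline_t2star,
                 activation_delta = activation_delta,
                 transition_tau = transition_tau),
            class = "svps_bold")
}

#' Nuisance model for the simulator
#'
#' Emulates the artefacts the real-time conditioning chain exists to remove:
#' additive complex Gaussian sampling noise, a slow sinusoidal T2* drift
#' with per-session random phase, sporadic repetition-level T2* spikes, and
#' a slow random walk of the water centre frequency (B0 wander).
#'
#' @param complex_noise_sd Standard deviation of each quadrature of the
#'   additive complex Gaussian noise, in signal units per sample. The
#'   default 0.008 is calibrated so a default session (water amplitude 1)
#'   yields a raw-series CNR near 3 and block t-values in the low twenties,
#'   the quality regime typical of 7 T unsuppressed-water sessions.
#' @param drift_amplitude Amplitude of the slow additive T2* drift, seconds
#'   (default 0.002, i.e. about 2.4 percent of the default baseline T2*).
#' @param drift_period Drift period in seconds (default 240).
#' @param drift_phase Drift phase in radians, or `NULL` (default) to draw it
#'   uniformly per session — scanner drift has arbitrary phase relative to
#'   the paradigm.
#' @param spike_prob Per-repetition probability of a T2* spike (default 0.02).
#' @param spike_scale Spike magnitude as a multiple of the SD of the clean
#'   T2* series (default 8, a clear outlier well above the noise while still
#'   physically conceivable for a single corrupted acquisition; stress tests
#'   of the spike gate typically inject far larger values).
#' @param b0_wander_sd Per-repetition standard deviation of the
#'   centre-frequency random-walk increments, Hz (default 0.2).
#'
#' @return A list with class `svps_noise`.
#' @export
svps_noise <- function(complex_noise_sd = 0.008,
                       drift_amplitude = 0.002,
                       drift_period = 240,
                       drift_phase = NULL,
                       spike_prob = 0.02,
                       spike_scale = 8,
                       b0_wander_sd = 0.2) {
  check_number(complex_noise_sd, "complex_noise_sd", lower = 0)
  check_number(drift_amplitude, "drift_amplitude", lower = 0)
  check_number(drift_period, "drift_period", lower = .Machine$double.eps)
  if (!is.null(drift_phase)) check_number(drift_phase, "drift_phase")
  check_number(spike_prob, "spike_prob", lower = 0, upper = 1)
  check_number(spike_scale, "spike_scale", lower = 0)
  check_number(b0_wander_sd, "b0_wander_sd", lower = 0)
  structure(list(complex_noise_sd = complex_noise_sd,
                 drift_amplitude = drift_amplitude,
                 drift_period = drift_period,
                 drift_phase = drift_phase,
                 spike_prob = spike_prob,
                 spike_scale = spike_scale,
                 b0_wander_sd = b0_wander_sd),
            class = "svps_noise")
}

#' Default water and contaminant components
#'
#' `svps_water()` is the unsuppressed water line (amplitude 1, on carrier,
#' baseline T2* 84.2 ms). `svps_contaminants()` is a single residual
#' off-resonance line 150 Hz from water, emulating the lipid/metabolite
#' contamination the Gaussian spectral window suppresses.
#'
#' @return An `svps_components` tibble.
#' @export
svps_water <- function() {
  svps_components(amplitude = 1, frequency = 0, phase = 0.3, t2star = 0.0842)
}

#' @rdname svps_water
#' @export
svps_contaminants <- function() {
  svps_components(amplitude = 0.1, frequency = -150, phase = 1, t2star = 0.03)
}
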