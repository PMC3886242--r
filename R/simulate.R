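#' Generate one FID frame
#'
#' Synthesises a complex free-induction decay as a sum of exponentially
#' decaying oscillators,
#' `s(t_k) = sum_j A_j exp(i 2 pi f_j t_k) exp(i phi_j) exp(-t_k / T2*_j)`,
#' with `t_k = k / bandwidth`, plus additive complex Gaussian noise
#' (independent N(0, noise_sd^2) on each quadrature).
#'
#' @param components An [svps_components] tibble.
#' @param acq An [svps_acquisition] object.
#' @param noise_sd Per-quadrature noise standard deviation (signal units).
#' @return An `svps_fid` object: list with complex `samples`, `bandwidth`,
#'   `te`.
#' @examples
#' fid <- generate_fid(svps_water(), svps_acquisition())
#' Mod(fid$samples[1])
#' @export
generate_fid <- function(components, acq, noise_sd = 0) {
  stopifnot(inherits(acq, "svps_acquisition"))
  if (!inherits(components, "svps_components")) {
    components <- svps_components(components$amplitude, components$frequency,
                                  components$phase, components$t2star)
  }
  check_number(noise_sd, "noise_sd", lower = 0)
  if (any(abs(components$frequency) >= acq$bandwidth / 2)) {
    svps_abort("component frequencies must satisfy |f| < bandwidth / 2",
               class = "svps_config_error")
  }
  t <- acq_time(acq)
  samples <- component_signal(components, t)
  if (noise_sd > 0) {
    samples <- samples + complex(real = rnorm(length(t), 0, noise_sd),
                                 imaginary = rnorm(length(t), 0, noise_sd))
  }
  new_svps_fid(samples, acq)
}

new_svps_fid <- function(samples, acq) {
  structure(list(samples = samples, bandwidth = acq$bandwidth, te = acq$te),
            class = "svps_fid")
}

component_signal <- function(components, t) {
  sig <- rep(0 + 0i, length(t))
  for (j in seq_len(nrow(components))) {
    sig <- sig + components$amplitude[j] *
      exp(1i * (2 * pi * components$frequency[j] * t + components$phase[j])) *
      exp(-t / components$t2star[j])
  }
  sig
}

#' @export
print.svps_fid <- function(x, ...) {
  cat(sprintf("<svps_fid> %d complex samples, bandwidth %g Hz, TE %g s\n",
              length(x$samples), x$bandwidth, x$te))
  invisible(x)
}

#' @export
as_tibble.svps_fid <- function(x, ...) {
  n <- length(x$samples)
  tibble(sample = seq_len(n),
         time_s = (seq_len(n) - 1) / x$bandwidth,
         real = Re(x$samples),
         imag = Im(x$samples))
}

# first-order two-state response of T2* to the block labels
bold_t2star_series <- function(design, bold) {
  target <- ifelse(design$labels == "activation",
                   bold$baseline_t2star * (1 + bold$activation_delta),
                   bold$baseline_t2star)
  if (bold$transition_tau <= 0) return(target)
  a <- exp(-design$tr / bold$transition_tau)
  out <- numeric(design$n_reps)
  state <- bold$baseline_t2star
  for (i in seq_len(design$n_reps)) {
    state <- target[i] + (state - target[i]) * a
    out[i] <- state
  }
  out
}

#' Simulate a full SVPS session
#'
#' Generates one FID frame per repetition. The water component's T2* follows
#' the block design through the [svps_bold] model; the nuisance model adds a
#' slow sinusoidal T2* drift, sporadic additive T2* spikes
#' (`spike_scale` times the SD of the clean T2* series), a random walk of
#' the water centre frequency, and complex Gaussian sampling noise. The
#' returned ground truth separates the BOLD-driven T2* (`true_t2star`) from
#' the nuisance contributions actually realised in the frames
#' (`realized_t2star`).
#'
#' Output is fully reproducible for a fixed `seed`.
#'
#' @param design An [svps_design].
#' @param bold An [svps_bold] model.
#' @param water A one-row [svps_components] tibble for the water line; its
#'   `t2star` column is overridden per repetition by the BOLD model.
#' @param contaminants An [svps_components] tibble of off-resonance lines
#'   (may have zero rows).
#' @param acq An [svps_acquisition].
#' @param noise An [svps_noise] model.
#' @param seed Integer RNG seed.
#'
#' @return An `svps_session`: list with
#'   \item{fids}{complex matrix, `n_points` x `n_reps`;}
#'   \item{truth}{tibble with per-repetition `rep`, `label`, `discarded`,
#'     `true_t2star`, `drift`, `realized_t2star`, `center_freq_hz`,
#'     `spike`;}
#'   \item{design, acq, params}{the inputs, for provenance.}
#' @examples
#' ses <- simulate_session(design = svps_design(block_len = 5, n_blocks = 2,
#'                                              n_discard = 2),
#'                         acq = svps_acquisition(n_points = 64), seed = 1)
#' ses$truth
#' @export
simulate_session <- function(design = svps_design(),
                             bold = svps_bold(),
                             water = svps_water(),
                             contaminants = svps_contaminants(),
                             acq = svps_acquisition(),
                             noise = svps_noise(),
                             seed = 1L) {
  stopifnot(inherits(design, "svps_design"), inherits(bold, "svps_bold"),
            inherits(acq, "svps_acquisition"), inherits(noise, "svps_noise"))
  set.seed(as.integer(seed))
  n <- design$n_reps
  t_rep <- (seq_len(n) - 1) * design$tr

  true_t2 <- bold_t2star_series(design, bold)

  drift_phase <- noise$drift_phase %||% runif(1, 0, 2 * pi)
  drift <- noise$drift_amplitude *
    sin(2 * pi * t_rep / noise$drift_period + drift_phase)

  spike <- runif(n) < noise$spike_prob
  clean_sd <- sd(true_t2 + drift)
  spike_ref <- if (clean_sd > 0) clean_sd else 0.01 * bold$baseline_t2star
  realized_t2 <- true_t2 + drift + ifelse(spike, noise$spike_scale * spike_ref, 0)
  realized_t2 <- pmax(realized_t2, .Machine$double.eps)

  center_freq <- water$frequency[1] +
    cumsum(rnorm(n, 0, noise$b0_wander_sd))

  t <- acq_time(acq)
  fids <- matrix(0 + 0i, nrow = acq$n_points, ncol = n)
  contam_sig <- if (nrow(contaminants) > 0) {
    component_signal(contaminants, t)
  } else {
    rep(0 + 0i, length(t))
  }
  for (i in seq_len(n)) {
    comp <- svps_components(amplitude = water$amplitude[1],
                            frequency = center_freq[i],
                            phase = water$phase[1],
                            t2star = realized_t2[i])
    sig <- component_signal(comp, t) + contam_sig
    if (noise$complex_noise_sd > 0) {
      sig <- sig + complex(real = rnorm(length(t), 0, noise$complex_noise_sd),
                           imaginary = rnorm(length(t), 0, noise$complex_noise_sd))
    }
    fids[, i] <- sig
  }

  truth <- tibble(rep = seq_len(n),
                  label = design$labels,
                  discarded = seq_len(n) <= design$n_discard,
                  true_t2star = true_t2,
                  drift = drift,
                  realized_t2star = realized_t2,
                  center_freq_hz = center_freq,
                  spike = spike)

  structure(list(fids = fids, truth = truth, design = design, acq = acq,
                 params = list(bold = bold, water = water,
                               contaminants = contaminants, noise = noise,
                               seed = as.integer(seed))),
            class = "svps_session")
}

#' @export
print.svps_session <- function(x, ...) {
  cat(sprintf(paste0("<svps_session> %d repetitions (%d discarded), ",
                     "%d points/FID, TR %g s\n"),
              x$design$n_reps, x$design$n_discard, x$acq$n_points,
              x$design$tr))
  cat(sprintf("  spikes: %d, baseline T2* %g s, activation delta %+g%%\n",
              sum(x$truth$spike), x$params$bold$baseline_t2star,
              100 * x$params$bold$activation_delta))
  invisible(x)
}

# one frame of a session as an svps_fid
session_frame <- function(session, i) {
  new_svps_fid(session$fids[, i], session$acq)
}

#' @describeIn simulate_session Long-format view of the frames: one row per
#'   (repetition, sample) with columns `rep`, `sample`, `time_s`, `real`,
#'   `imag`.
#' @param x,... Method arguments.
#' @export
as_tibble.svps_session <- function(x, ...) {
  n_pt <- x$acq$n_points
  n_rep <- x$design$n_reps
  tibble(rep = rep(seq_len(n_rep), each = n_pt),
         sample = rep(seq_len(n_pt), times = n_rep),
         time_s = rep(acq_time(x$acq), times = n_rep),
         real = as.vector(Re(x$fids)),
         imag = as.vector(Im(x$fids)))
}
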