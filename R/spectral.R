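#' Discrete spectrum of an FID frame
#'
#' Unnormalised DFT of the complex samples, with bin frequencies spanning
#' `(-bandwidth/2, bandwidth/2]` (the Nyquist bin is mapped to
#' `+bandwidth/2`). The transform is invertible: [from_spectrum()] recovers
#' the frame to numerical precision.
#'
#' @param frame An `svps_fid`.
#' @return An `svps_spectrum`: list with complex `values`, `freqs` (Hz, in
#'   native FFT bin order) and `bandwidth`.
#' @export
to_spectrum <- function(frame) {
  stopifnot(inherits(frame, "svps_fid"))
  n <- length(frame$samples)
  if (n < 1L) svps_abort("empty frame", class = "svps_data_error")
  structure(list(values = fft(frame$samples),
                 freqs = bin_freqs(n, frame$bandwidth),
                 bandwidth = frame$bandwidth,
                 te = frame$te),
            class = "svps_spectrum")
}

# bin k (0-based) -> k*bw/N for k <= N/2, (k-N)*bw/N above; Nyquist at +bw/2
bin_freqs <- function(n, bandwidth) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * bandwidth / n
}

#' @rdname to_spectrum
#' @param spec An `svps_spectrum`.
#' @export
from_spectrum <- function(spec) {
  stopifnot(inherits(spec, "svps_spectrum"))
  samples <- fft(spec$values, inverse = TRUE) / length(spec$values)
  structure(list(samples = samples, bandwidth = spec$bandwidth, te = spec$te),
            class = "svps_fid")
}

#' @export
as_tibble.svps_spectrum <- function(x, ...) {
  ord <- order(x$freqs)
  tibble(freq_hz = x$freqs[ord],
         value = x$values[ord],
         magnitude = Mod(x$values)[ord])
}

#' Locate the water peak
#'
#' Frequency of the maximum-magnitude spectral bin, refined by three-point
#' parabolic interpolation on the log-magnitude (exact for a Gaussian line,
#' a good sub-bin estimate for a Lorentzian water line).
#'
#' @param spec An `svps_spectrum`.
#' @return Peak frequency in Hz.
#' @export
find_water_peak <- function(spec) {
  stopifnot(inherits(spec, "svps_spectrum"))
  mag <- Mod(spec$values)
  if (all(mag == 0)) svps_abort("all-zero spectrum has no peak",
                                class = "svps_data_error")
  n <- length(mag)
  k0 <- which.max(mag)
  km <- if (k0 == 1L) n else k0 - 1L
  kp <- if (k0 == n) 1L else k0 + 1L
  y <- log(pmax(mag[c(km, k0, kp)], .Machine$double.xmin))
  denom <- y[1] - 2 * y[2] + y[3]
  delta <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
  delta <- max(min(delta, 0.5), -0.5)
  s0 <- k0 - 1L
  if (s0 > n / 2) s0 <- s0 - n
  (s0 + delta) * spec$bandwidth / n
}

#' Shift a frame's centre frequency to zero
#'
#' Multiplies the time-domain samples by `exp(-i 2 pi f t_k)` so that a
#' component at `peak_freq` lands on zero frequency, the precondition for
#' the single-line log-linear model.
#'
#' @param frame An `svps_fid`.
#' @param peak_freq Frequency to remove, Hz; `|peak_freq|` must be below
#'   half the bandwidth.
#' @return The shifted `svps_fid`.
#' @export
shift_to_center <- function(frame, peak_freq) {
  stopifnot(inherits(frame, "svps_fid"))
  check_number(peak_freq, "peak_freq")
  if (abs(peak_freq) >= frame$bandwidth / 2) {
    svps_abort("|peak_freq| must be below bandwidth / 2",
               class = "svps_data_error")
  }
  t <- (seq_along(frame$samples) - 1) / frame$bandwidth
  frame$samples <- frame$samples * exp(-1i * 2 * pi * peak_freq * t)
  frame
}

#' Gaussian spectral window
#'
#' Multiplies each spectral value by `exp(-f^2 / (2 sigma^2))`. Applied
#' after [shift_to_center()], so the window is centred on the water line and
#' suppresses off-resonance contamination (lipids, metabolites) while
#' passing the few-Hz-wide water line essentially untouched.
#'
#' @param spec An `svps_spectrum`.
#' @param sigma Window width in Hz (default 20). `Inf` disables the window.
#' @return The filtered `svps_spectrum`.
#' @export
gaussian_window <- function(spec, sigma = 20) {
  stopifnot(inherits(spec, "svps_spectrum"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0) {
    svps_abort("`sigma` must be a single positive number",
               class = "svps_config_error")
  }
  if (is.finite(sigma)) {
    spec$values <- spec$values * exp(-spec$freqs^2 / (2 * sigma^2))
  }
  spec
}

#' Spectral conditioning of one frame
#'
#' The full per-frame front end: locate the water peak, shift it to zero
#' frequency, and apply the Gaussian spectral window. Returns the processed
#' time-domain frame together with the detected peak frequency.
#'
#' @param frame An `svps_fid`.
#' @param config An [svps_filter] configuration.
#' @return A list: `frame` (processed `svps_fid`), `peak_freq_hz`.
#' @export
condition_frame <- function(frame, config = svps_filter()) {
  peak <- find_water_peak(to_spectrum(frame))
  shifted <- shift_to_center(frame, peak)
  windowed <- from_spectrum(gaussian_window(to_spectrum(shifted),
                                            sigma = config$gaussian_sigma))
  list(frame = windowed, peak_freq_hz = peak)
}
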