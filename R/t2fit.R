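#' Spectral filter / regression configuration
#'
#' @param gaussian_sigma Width of the Gaussian spectral window in Hz
#'   (default 20): wide enough to pass the few-Hz water line after shimming,
#'   narrow enough to suppress lipid/metabolite lines >= ~100 Hz off-water
#'   at 7 T.
#' @param regression_length Early-FID segment length `l` in seconds used for
#'   the log-linear fit (default 0.2, the order of magnitude at which
#'   session t-values typically peak).
#' @param min_fit_points Minimum number of samples a regression window must
#'   contain (default 3).
#' @param fit_start Start of the regression window in seconds. The Gaussian
#'   spectral window acts in time as convolution with a kernel of width
#'   `1 / (2 pi gaussian_sigma)`; away from the acquisition edges this
#'   leaves an exponential exactly proportional to itself, but it smears
#'   the first few samples and would bias the decay slope. The default
#'   (`NULL`) therefore starts the fit three kernel widths in,
#'   `3 / (2 pi gaussian_sigma)` (0 when the window is disabled), which
#'   removes the edge bias to numerical precision.
#' @return A list with class `svps_filter`.
#' @export
svps_filter <- function(gaussian_sigma = 20, regression_length = 0.2,
                        min_fit_points = 3, fit_start = NULL) {
  if (!(is.numeric(gaussian_sigma) && length(gaussian_sigma) == 1L &&
        !is.na(gaussian_sigma) && gaussian_sigma > 0)) {
    svps_abort("`gaussian_sigma` must be a single positive number (Inf allowed)",
               class = "svps_config_error")
  }
  check_number(regression_length, "regression_length",
               lower = .Machine$double.eps)
  check_number(min_fit_points, "min_fit_points", lower = 2)
  if (is.null(fit_start)) {
    fit_start <- if (is.finite(gaussian_sigma)) 3 / (2 * pi * gaussian_sigma) else 0
  }
  check_number(fit_start, "fit_start", lower = 0)
  structure(list(gaussian_sigma = gaussian_sigma,
                 regression_length = regression_length,
                 min_fit_points = as.integer(min_fit_points),
                 fit_start = fit_start),
            class = "svps_filter")
}

# 2*pi jump correction along the time axis
unwrap_phase <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  phi[1] + c(0, cumsum(d - 2 * pi * round(d / (2 * pi))))
}

# index of the first fitted sample for a regression start time
start_index <- function(t_start, bandwidth) {
  as.integer(round(t_start * bandwidth)) + 1L
}

# samples covered by a regression length l starting at index k0
window_points <- function(l, bandwidth, n_points, k0 = 1L) {
  n_l <- min(floor(l * bandwidth + 1e-9) + 1L, n_points - k0 + 1L)
  as.integer(n_l)
}

#' Log-linear T2* fit of a conditioned FID
#'
#' After the centre-frequency shift the conditioned FID is modelled as a
#' single decaying line, `ln FID(t) = -t/T2* + ln A + i phi`, a complex
#' straight line in `t`. The fit is realised as two real ordinary
#' least-squares fits over `t` in `[0, l]`: the log-magnitude gives the
#' slope (`-1/T2*`) and `ln A`; the unwrapped phase gives `phi` and any
#' residual frequency. A non-negative magnitude slope means the decay
#' constant is undefined; the estimate is then returned with
#' `fit_ok = FALSE` (callers typically carry the previous valid estimate
#' forward).
#'
#' @param frame A conditioned `svps_fid` (already shifted and windowed).
#' @param l Regression length in seconds.
#' @param min_fit_points Minimum samples in the window.
#' @param t_start Start of the regression window in seconds (default 0);
#'   see [svps_filter()] for why windowed frames are fitted from a small
#'   offset. Amplitude and phase are always extrapolated to t = 0.
#' @return A one-row tibble: `t2star`, `amplitude`, `phase`,
#'   `freq_resid_hz`, `residual_rms`, `length_used`, `n_fit`, `fit_ok`.
#' @examples
#' fid <- generate_fid(svps_components(1, 0, 0, 0.05),
#'                     svps_acquisition(n_points = 64))
#' loglinear_t2(fid, l = 0.05)
#' @export
loglinear_t2 <- function(frame, l, min_fit_points = 3, t_start = 0) {
  stopifnot(inherits(frame, "svps_fid"))
  check_number(l, "l", lower = .Machine$double.eps)
  check_number(t_start, "t_start", lower = 0)
  n <- length(frame$samples)
  k0 <- start_index(t_start, frame$bandwidth)
  n_l <- window_points(l, frame$bandwidth, n, k0)
  if (n_l < min_fit_points) {
    svps_abort(sprintf("regression length %g s covers %d samples; need >= %d",
                       l, n_l, min_fit_points),
               class = "svps_config_error")
  }
  y <- frame$samples[seq.int(k0, k0 + n_l - 1L)]
  mag <- Mod(y)
  if (any(mag <= 0)) {
    svps_abort("zero magnitude inside the regression window (degenerate signal)",
               class = "svps_data_error")
  }
  t <- (seq.int(k0, k0 + n_l - 1L) - 1) / frame$bandwidth
  lnmag <- log(mag)
  ph <- unwrap_phase(Arg(y))

  tb <- mean(t)
  stt <- sum((t - tb)^2)
  slope_r <- sum((t - tb) * lnmag) / stt
  icpt_r <- mean(lnmag) - slope_r * tb
  slope_i <- sum((t - tb) * ph) / stt
  icpt_i <- mean(ph) - slope_i * tb

  res <- complex(real = lnmag - (icpt_r + slope_r * t),
                 imaginary = ph - (icpt_i + slope_i * t))
  fit_ok <- slope_r < 0
  tibble(t2star = if (fit_ok) -1 / slope_r else NA_real_,
         amplitude = exp(icpt_r),
         phase = icpt_i,
         freq_resid_hz = slope_i / (2 * pi),
         residual_rms = sqrt(mean(Mod(res)^2)),
         length_used = (n_l - 1) / frame$bandwidth,
         n_fit = n_l,
         fit_ok = fit_ok)
}
# NOTE: slope/intercept use absolute t, so amplitude and phase refer to t = 0
# even when the window starts at t_start.

#' Estimate T2* from one raw FID frame
#'
#' Runs the full spectral chain on a raw frame — water-peak detection,
#' centre-frequency shift, Gaussian windowing — followed by the log-linear
#' regression of [loglinear_t2()].
#'
#' @param frame A raw `svps_fid`.
#' @param config An [svps_filter] configuration.
#' @return A one-row tibble as in [loglinear_t2()], plus `peak_freq_hz`.
#' @export
estimate_t2star <- function(frame, config = svps_filter()) {
  cond <- condition_frame(frame, config)
  out <- loglinear_t2(cond$frame, l = config$regression_length,
                      min_fit_points = config$min_fit_points,
                      t_start = config$fit_start)
  out$peak_freq_hz <- cond$peak_freq_hz
  out
}

#' Per-repetition T2* series of a session
#'
#' Applies [estimate_t2star()] to every frame of a session. Failed fits
#' (non-negative log-magnitude slope) carry the previous valid T2* forward;
#' leading failures take the first valid value. A warning reports the
#' number of carried-forward frames.
#'
#' @param session An `svps_session`.
#' @param config An [svps_filter] configuration.
#' @return A tibble with one row per repetition: `rep`, `label`,
#'   `discarded`, `t2star`, `amplitude`, `phase`, `freq_resid_hz`,
#'   `residual_rms`, `peak_freq_hz`, `fit_ok`.
#' @export
t2star_series <- function(session, config = svps_filter()) {
  stopifnot(inherits(session, "svps_session"))
  n <- session$design$n_reps
  bw <- session$acq$bandwidth
  pre <- preprocess_session(session, config)
  k0 <- start_index(config$fit_start, bw)
  n_l <- window_points(config$regression_length, bw, session$acq$n_points, k0)
  if (n_l < config$min_fit_points) {
    svps_abort(sprintf("regression length %g s covers %d samples; need >= %d",
                       config$regression_length, n_l, config$min_fit_points),
               class = "svps_config_error")
  }
  idx <- seq.int(k0, k0 + n_l - 1L)
  t <- pre$time[idx]
  tb <- mean(t)
  stt <- sum((t - tb)^2)

  lnm <- pre$lnmag[idx, , drop = FALSE]
  bad <- apply(lnm, 2, anyNA)
  slope_r <- colSums((t - tb) * lnm) / stt
  icpt_r <- colMeans(lnm) - slope_r * tb

  ph <- Arg(pre$processed[idx, , drop = FALSE])
  if (n_l > 1L) {
    d <- apply(ph, 2, diff)
    if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
    d <- d - 2 * pi * round(d / (2 * pi))
    steps <- apply(d, 2, cumsum)
    if (is.null(dim(steps))) steps <- matrix(steps, nrow = 1L)
    ph <- rbind(ph[1, ], sweep(steps, 2, ph[1, ], "+"))
  }
  slope_i <- colSums((t - tb) * ph) / stt
  icpt_i <- colMeans(ph) - slope_i * tb

  res2 <- (lnm - outer(t, slope_r) -
             matrix(icpt_r, n_l, n, byrow = TRUE))^2 +
    (ph - outer(t, slope_i) - matrix(icpt_i, n_l, n, byrow = TRUE))^2
  fit_ok <- !bad & is.finite(slope_r) & slope_r < 0

  out <- tibble(rep = seq_len(n),
                label = session$design$labels,
                discarded = seq_len(n) <= session$design$n_discard,
                t2star = ifelse(fit_ok, -1 / slope_r, NA_real_),
                amplitude = exp(icpt_r),
                phase = icpt_i,
                freq_resid_hz = slope_i / (2 * pi),
                residual_rms = sqrt(colMeans(res2)),
                length_used = (n_l - 1) / bw,
                n_fit = n_l,
                fit_ok = fit_ok,
                peak_freq_hz = pre$peaks)
  n_bad <- sum(!out$fit_ok)
  if (n_bad > 0) {
    warn(sprintf("%d of %d frames had an undefined decay; previous estimate carried forward",
                 n_bad, n))
    out$t2star <- carry_forward(out$t2star)
  }
  out
}

# replace NAs with the last preceding valid value; leading NAs take the
# first valid value
carry_forward <- function(x) {
  if (!anyNA(x)) return(x)
  ok <- which(!is.na(x))
  if (length(ok) == 0L) {
    svps_abort("no frame produced a valid T2* estimate",
               class = "svps_numeric_error")
  }
  idx <- findInterval(seq_along(x), ok)
  x[ok[pmax(idx, 1L)]]
}
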