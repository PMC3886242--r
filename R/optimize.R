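#' Optimise the log-linear regression length for a session
#'
#' The usable early portion of the FID depends on shim quality and residual
#' contamination, so the regression length `l` is tuned per voxel on a
#' labelled (non-feedback) session: for every candidate `l` the full
#' per-repetition T2* series is computed and scored with the block-design
#' GLM t-value ([block_glm_tvalue()]) over the retained repetitions. The
#' optimum is the candidate maximising the t-value; ties are broken towards
#' the shorter length (shorter sampling favours speed).
#'
#' Frame conditioning (peak shift + Gaussian window) does not depend on
#' `l`, so it is performed once and each candidate only refits the
#' log-magnitude line.
#'
#' @param session An `svps_session` from a labelled session.
#' @param candidate_lengths Candidate lengths in seconds; default is every
#'   sample count from 16 points up to the full FID.
#' @param config An [svps_filter]; its `regression_length` is ignored here.
#' @return An `svps_lcurve`: list with `l_optim` (seconds), `t_optim`, and
#'   `t_curve`, a tibble (`length_s`, `n_fit`, `t_value`).
#' @export
optimize_regression_length <- function(session, candidate_lengths = NULL,
                                       config = svps_filter()) {
  stopifnot(inherits(session, "svps_session"))
  bw <- session$acq$bandwidth
  n_pts <- session$acq$n_points
  k0 <- start_index(config$fit_start, bw)
  if (is.null(candidate_lengths)) {
    candidate_lengths <- (seq.int(16L, n_pts - k0 + 1L) - 1L) / bw
  }
  if (length(candidate_lengths) < 1L) {
    svps_abort("at least one candidate length is required",
               class = "svps_config_error")
  }

  pre <- preprocess_session(session, config)
  retain <- retained_reps(session$design)
  labels <- session$design$labels[retain]

  t_vals <- rep(NA_real_, length(candidate_lengths))
  for (ci in seq_along(candidate_lengths)) {
    l <- candidate_lengths[ci]
    n_l <- window_points(l, bw, n_pts, k0)
    if (n_l < config$min_fit_points) next
    t2 <- fit_t2_window(pre$lnmag, pre$time, n_l, k0)
    if (all(is.na(t2))) next
    t2 <- carry_forward(t2)
    t_vals[ci] <- tryCatch(block_glm_tvalue(t2[retain], labels),
                           svps_error = function(e) NA_real_)
  }
  if (all(is.na(t_vals))) {
    svps_abort("regression-length optimisation failed for every candidate",
               class = "svps_numeric_error")
  }
  best <- which(t_vals == max(t_vals, na.rm = TRUE))
  best <- best[which.min(candidate_lengths[best])]

  structure(list(l_optim = candidate_lengths[best],
                 t_optim = t_vals[best],
                 t_curve = tibble(
                   length_s = candidate_lengths,
                   n_fit = vapply(candidate_lengths, window_points,
                                  integer(1), bandwidth = bw,
                                  n_points = n_pts, k0 = k0),
                   t_value = t_vals)),
            class = "svps_lcurve")
}

# condition every frame once (vectorised across frames with mvfft; same
# arithmetic as condition_frame on a single frame); returns the processed
# complex matrix, its log-magnitude, the per-frame peak and the time axis
preprocess_session <- function(session, config) {
  fids <- session$fids
  n_pt <- nrow(fids)
  bw <- session$acq$bandwidth
  t <- acq_time(session$acq)

  sp <- stats::mvfft(fids)
  mag <- Mod(sp)
  if (any(colSums(mag) == 0)) {
    svps_abort("all-zero spectrum has no peak", class = "svps_data_error")
  }
  k0v <- max.col(t(mag), ties.method = "first")
  j <- seq_len(ncol(fids))
  km <- ifelse(k0v == 1L, n_pt, k0v - 1L)
  kp <- ifelse(k0v == n_pt, 1L, k0v + 1L)
  y1 <- log(pmax(mag[cbind(km, j)], .Machine$double.xmin))
  y2 <- log(pmax(mag[cbind(k0v, j)], .Machine$double.xmin))
  y3 <- log(pmax(mag[cbind(kp, j)], .Machine$double.xmin))
  denom <- y1 - 2 * y2 + y3
  delta <- ifelse(denom < 0, 0.5 * (y1 - y3) / denom, 0)
  delta <- pmax(pmin(delta, 0.5), -0.5)
  s0 <- k0v - 1L
  s0 <- ifelse(s0 > n_pt / 2, s0 - n_pt, s0)
  peaks <- (s0 + delta) * bw / n_pt

  shifted <- fids * exp(-1i * 2 * pi * outer(t, peaks))
  sp2 <- stats::mvfft(shifted)
  if (is.finite(config$gaussian_sigma)) {
    w <- exp(-bin_freqs(n_pt, bw)^2 / (2 * config$gaussian_sigma^2))
    sp2 <- sp2 * w
  }
  proc <- stats::mvfft(sp2, inverse = TRUE) / n_pt

  pmag <- Mod(proc)
  lnmag <- suppressWarnings(log(pmag))
  lnmag[pmag <= 0] <- NA_real_
  list(processed = proc, lnmag = lnmag, peaks = peaks, time = t)
}

# vectorised log-magnitude slope over n_l samples from index k0 of each
# column; identical arithmetic to loglinear_t2()'s magnitude fit
fit_t2_window <- function(lnmag, time, n_l, k0 = 1L) {
  idx <- seq.int(k0, k0 + n_l - 1L)
  t <- time[idx]
  tb <- mean(t)
  stt <- sum((t - tb)^2)
  w <- lnmag[idx, , drop = FALSE]
  slopes <- colSums((t - tb) * w) / stt
  t2 <- -1 / slopes
  t2[!is.finite(slopes) | slopes >= 0] <- NA_real_
  t2
}

#' @export
print.svps_lcurve <- function(x, ...) {
  cat(sprintf("<svps_lcurve> %d candidates; l_optim = %g s (t = %.3f)\n",
              nrow(x$t_curve), x$l_optim, x$t_optim))
  invisible(x)
}

#' @export
tidy.svps_lcurve <- function(x, ...) x$t_curve

#' @export
glance.svps_lcurve <- function(x, ...) {
  tibble(l_optim_s = x$l_optim, t_optim = x$t_optim,
         n_candidates = nrow(x$t_curve),
         n_failed = sum(is.na(x$t_curve$t_value)))
}

#' @export
autoplot.svps_lcurve <- function(object, ...) {
  ggplot2::ggplot(object$t_curve,
                  ggplot2::aes(x = .data$length_s, y = .data$t_value)) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::geom_point(data = tibble(length_s = object$l_optim,
                                      t_value = object$t_optim),
                        colour = "red", size = 2) +
    ggplot2::labs(x = "regression length l (s)",
                  y = "block-design t-value",
                  title = "Regression-length optimisation") +
    ggplot2::theme_minimal()
}
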