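#' Contrast-to-noise ratio of a block-design series
#'
#' `CNR = (mean(cond) - mean(bas)) / sqrt(var(cond) + var(bas))` with
#' sample variances (n - 1 denominator), measuring the sensitivity of the
#' series to the block contrast. Scale-invariant.
#'
#' @param series Numeric per-repetition values, or a data frame holding the
#'   series and labels.
#' @param labels Condition labels (`"baseline"` / `"activation"`), or, when
#'   `series` is a data frame, the names of the value and label columns.
#' @param value,label Column names used when `series` is a data frame.
#' @return A single number.
#' @examples
#' cnr(c(1, 1.2, 0.8, 2, 2.2, 1.8),
#'     rep(c("baseline", "activation"), each = 3))
#' @export
cnr <- function(series, labels = NULL, value = "t2star", label = "label") {
  s <- resolve_series(series, labels, value, label)
  st <- block_stats(s$series, s$labels)
  denom <- st$var_cond + st$var_bas
  if (denom <= 0) svps_abort("zero total variance: CNR undefined",
                             class = "svps_numeric_error")
  (st$mean_cond - st$mean_bas) / sqrt(denom)
}

#' Percent signal change of a block-design series
#'
#' `(mean(cond) - mean(bas)) / mean(bas)`, the fractional change of the
#' activation blocks over baseline; computable without any scaling and
#' invariant to multiplying the series by a positive constant.
#'
#' @inheritParams cnr
#' @return The fractional change (0.05 means +5 percent).
#' @export
percent_change <- function(series, labels = NULL, value = "t2star",
                           label = "label") {
  s <- resolve_series(series, labels, value, label)
  st <- block_stats(s$series, s$labels)
  if (st$mean_bas == 0) svps_abort("zero baseline mean: percent change undefined",
                                   class = "svps_numeric_error")
  (st$mean_cond - st$mean_bas) / st$mean_bas
}

resolve_series <- function(series, labels, value, label) {
  if (is.data.frame(series)) {
    list(series = series[[value]], labels = series[[label]])
  } else {
    list(series = series, labels = labels)
  }
}

# condition-wise means and variances (n - 1 denominator)
block_stats <- function(series, labels) {
  stopifnot(length(series) == length(labels))
  keep <- !is.na(series)
  series <- series[keep]
  labels <- labels[keep]
  cond <- series[labels == "activation"]
  bas <- series[labels == "baseline"]
  if (length(cond) < 2L || length(bas) < 2L) {
    svps_abort("need >= 2 samples in each condition",
               class = "svps_data_error")
  }
  list(mean_cond = mean(cond), mean_bas = mean(bas),
       var_cond = var(cond), var_bas = var(bas),
       n_cond = length(cond), n_bas = length(bas))
}

#' Block-design GLM
#'
#' Ordinary least squares of the series on an intercept and the boxcar of
#' the activation labels; the reported t-value is the boxcar coefficient
#' over its standard error, with `n - 2` degrees of freedom. No motion
#' regressors enter the single-voxel model. Optionally the boxcar can be
#' convolved with a canonical double-gamma haemodynamic response (off by
#' default; with 30 s blocks the difference is minor).
#'
#' A series that reproduces the boxcar exactly has zero residual variance;
#' the t-value is then flagged infinite rather than reported as a number
#' from a degenerate fit.
#'
#' @inheritParams cnr
#' @param hrf Convolve the boxcar with a canonical HRF before fitting.
#' @param tr Sampling interval in seconds (used only for the HRF).
#' @return An `svps_glm` object; see [tidy()] and [glance()] methods.
#'   `block_glm_tvalue()` returns just the t-value (possibly `Inf`).
#' @export
block_glm <- function(series, labels = NULL, value = "t2star",
                      label = "label", hrf = FALSE, tr = 1) {
  s <- resolve_series(series, labels, value, label)
  y <- s$series
  lab <- s$labels
  keep <- !is.na(y)
  y <- y[keep]
  lab <- lab[keep]
  x <- as.numeric(lab == "activation")
  if (hrf) x <- convolve_hrf(x, tr)
  if (length(y) < 5L) {
    svps_abort("need at least 3 more samples than regressors",
               class = "svps_data_error")
  }
  if (var(x) == 0) {
    svps_abort("boxcar regressor is constant; both conditions required",
               class = "svps_data_error")
  }
  fit <- lm(y ~ x)
  # summary() warns on zero-residual fits; degeneracy is detected below
  sm <- suppressWarnings(summary(fit))
  sigma <- sm$sigma
  infinite <- !is.finite(sigma) || sigma < sqrt(.Machine$double.eps) * max(abs(y), 1)
  est <- unname(coef(fit)["x"])
  se <- sm$coefficients["x", "Std. Error"]
  tval <- if (infinite) Inf * sign(est) else est / se
  structure(list(fit = fit, estimate = est, se = se, t_value = tval,
                 dof = fit$df.residual, infinite = infinite, hrf = hrf),
            class = "svps_glm")
}

#' @rdname block_glm
#' @export
block_glm_tvalue <- function(series, labels = NULL, value = "t2star",
                             label = "label", hrf = FALSE, tr = 1) {
  block_glm(series, labels, value, label, hrf = hrf, tr = tr)$t_value
}

# canonical double-gamma HRF sampled at tr, peak normalised to 1
convolve_hrf <- function(x, tr) {
  t <- seq(0, 30, by = tr)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h <- h / max(h)
  full <- stats::convolve(x, rev(h), type = "open")
  full[seq_along(x)]
}

#' @export
print.svps_glm <- function(x, ...) {
  cat(sprintf("<svps_glm> boxcar t = %.3f (df = %d)%s\n", x$t_value, x$dof,
              if (x$infinite) " [degenerate: zero residual variance]" else ""))
  invisible(x)
}

#' @export
tidy.svps_glm <- function(x, ...) {
  sm <- suppressWarnings(summary(x$fit))
  tibble(term = c("(Intercept)", "boxcar"),
         estimate = unname(coef(x$fit)),
         std.error = sm$coefficients[, "Std. Error"],
         statistic = c(sm$coefficients["(Intercept)", "t value"],
                       x$t_value))
}

#' @export
glance.svps_glm <- function(x, ...) {
  tibble(t_value = x$t_value, estimate = x$estimate, std.error = x$se,
         dof = x$dof, degenerate = x$infinite,
         r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' Event-related average over baseline/activation cycles
#'
#' Cuts the retained series into complete baseline-plus-activation cycles
#' (one cycle = `2 * block_len` repetitions, aligned to the design's block
#' boundaries), and returns the position-wise mean and SD (n - 1) across
#' cycles. Cycles containing discarded or missing repetitions and any
#' partial trailing cycle are dropped.
#'
#' @param series Per-repetition values covering the full session
#'   (length `design$n_reps`; discarded positions may be `NA`), or an
#'   `svps_feedback` / data frame with the value column named by `value`.
#' @param design The [svps_design] of the session.
#' @param value Column name used when `series` is a data frame.
#' @return An `svps_event_avg` tibble: `position`, `time_s`, `label`,
#'   `cycle_mean`, `cycle_sd`; attribute `n_cycles`.
#' @export
event_average <- function(series, design, value = "filtered") {
  if (is.data.frame(series)) series <- series[[value]]
  stopifnot(inherits(design, "svps_design"))
  if (length(series) != design$n_reps) {
    svps_abort("series length must equal the design's repetition count",
               class = "svps_data_error")
  }
  cycle_len <- 2L * design$block_len
  usable <- !is.na(series) & seq_len(design$n_reps) > design$n_discard
  cycle_id <- (seq_len(design$n_reps) - 1L) %/% cycle_len + 1L
  complete <- vapply(split(usable, cycle_id), all, logical(1))
  keep_cycles <- as.integer(names(complete)[complete])
  if (length(keep_cycles) < 2L) {
    svps_abort("need >= 2 complete cycles for an event-related average",
               class = "svps_data_error")
  }
  m <- matrix(series[cycle_id %in% keep_cycles], nrow = cycle_len)
  out <- tibble(position = seq_len(cycle_len),
                time_s = (seq_len(cycle_len) - 1) * design$tr,
                label = design$labels[seq_len(cycle_len)],
                cycle_mean = rowMeans(m),
                cycle_sd = apply(m, 1, sd))
  class(out) <- c("svps_event_avg", class(out))
  attr(out, "n_cycles") <- length(keep_cycles)
  out
}

#' Event-related SNR
#'
#' Peak-to-peak amplitude of the event-related average divided by the mean
#' position-wise SD. This estimator is a package convention: it summarises
#' how large the time-locked response is relative to cycle-to-cycle
#' variability.
#'
#' @param ev An `svps_event_avg` from [event_average()].
#' @return A single number.
#' @export
event_snr <- function(ev) {
  stopifnot(inherits(ev, "svps_event_avg"))
  noise <- mean(ev$cycle_sd)
  if (noise <= 0) svps_abort("zero mean cycle SD: event SNR undefined",
                             class = "svps_numeric_error")
  (max(ev$cycle_mean) - min(ev$cycle_mean)) / noise
}

#' @export
autoplot.svps_event_avg <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s,
                                       y = .data$cycle_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$cycle_mean - .data$cycle_sd,
                                      ymax = .data$cycle_mean + .data$cycle_sd),
                         fill = "indianred", alpha = 0.3) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time within cycle (s)", y = "event-related average",
                  title = sprintf("Event-related average (%d cycles)",
                                  attr(object, "n_cycles"))) +
    ggplot2::theme_minimal()
}

#' Session-level quality metrics
#'
#' Scores a processed session the way offline quality control does: CNR and
#' the block-design GLM t-value on the conditioned series (detrended +
#' Kalman-filtered, i.e. everything but normalisation), percent signal
#' change on the raw T2* series with gate-flagged repetitions excluded
#' (the detrended series is zero-mean, so a percent baseline only exists
#' pre-detrend), and the event-related SNR of the conditioned series.
#'
#' @param feedback An `svps_feedback` tibble from [process_session()].
#' @param design The session's [svps_design]; defaults to reconstructing
#'   block structure from the feedback labels is not attempted — pass the
#'   design used for processing.
#' @return A one-row tibble: `cnr`, `percent`, `t_value`, `dof`,
#'   `event_snr`, `n_cycles`, `n_spikes`.
#' @export
session_metrics <- function(feedback, design) {
  stopifnot(inherits(feedback, "svps_feedback"), inherits(design, "svps_design"))
  ret <- dplyr::filter(as_tibble(feedback), !.data$discarded)
  cond_series <- ret$filtered
  g <- block_glm(cond_series, ret$label)
  raw_despiked <- ifelse(ret$spike %in% TRUE, NA_real_, ret$t2star_raw)
  # sessions shorter than two complete cycles simply have no event average
  ev <- tryCatch(event_average(feedback, design, value = "filtered"),
                 svps_data_error = function(e) NULL)
  tibble(cnr = cnr(cond_series, ret$label),
         percent = percent_change(raw_despiked, ret$label),
         t_value = g$t_value,
         dof = g$dof,
         event_snr = if (is.null(ev)) NA_real_ else event_snr(ev),
         n_cycles = if (is.null(ev)) 0L else attr(ev, "n_cycles"),
         n_spikes = sum(ret$spike, na.rm = TRUE))
}
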