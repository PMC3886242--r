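#' Initialise a streaming feedback pipeline
#'
#' Couples the spectral front end ([estimate_t2star()]) to the real-time
#' conditioning chain ([chain_step()]) for one-frame-per-TR processing.
#' The normalisation floor reference is taken from the first valid T2*
#' estimate unless supplied.
#'
#' @param filter An [svps_filter]; set `regression_length` to the session's
#'   optimised value from [optimize_regression_length()].
#' @param chain An [svps_chain].
#' @param floor_ref Optional normalisation floor reference (seconds).
#' @return An `svps_pipeline` state object for [process_frame()].
#' @export
pipeline_init <- function(filter = svps_filter(), chain = svps_chain(),
                          floor_ref = NULL) {
  structure(list(filter = filter, chain_config = chain,
                 chain_state = NULL, floor_ref = floor_ref,
                 last_t2 = NA_real_, n_carried = 0L),
            class = "svps_pipeline")
}

#' Process one raw FID frame through the full pipeline
#'
#' Spectral conditioning and T2* estimation followed by one step of the
#' EMA/Kalman/normalisation chain. A failed fit reuses the previous valid
#' T2* sample (counted in the pipeline state). Per-frame state is updated
#' exactly once.
#'
#' @param pipeline An `svps_pipeline` from [pipeline_init()] or a previous
#'   call.
#' @param frame A raw `svps_fid`.
#' @return A list: `pipeline` (updated) and `out`, a one-row tibble with
#'   `t2star_raw`, `fit_ok`, `peak_freq_hz`, `residual_rms`, `detrended`,
#'   `filtered`, `spike`, `feedback`.
#' @export
process_frame <- function(pipeline, frame) {
  est <- estimate_t2star(frame, pipeline$filter)
  t2 <- est$t2star
  if (!est$fit_ok) {
    t2 <- pipeline$last_t2
    pipeline$n_carried <- pipeline$n_carried + 1L
  }
  if (is.na(t2)) {
    # no valid estimate yet: nothing can enter the chain
    return(list(pipeline = pipeline,
                out = tibble(t2star_raw = NA_real_, fit_ok = FALSE,
                             peak_freq_hz = est$peak_freq_hz,
                             residual_rms = est$residual_rms,
                             detrended = NA_real_, filtered = NA_real_,
                             spike = NA, feedback = NA_real_)))
  }
  pipeline$last_t2 <- t2
  if (is.null(pipeline$chain_state)) {
    floor_ref <- pipeline$floor_ref %||% t2
    pipeline$chain_state <- chain_init(pipeline$chain_config,
                                       floor_ref = floor_ref)
  }
  st <- chain_step(pipeline$chain_state, t2)
  pipeline$chain_state <- st$state
  list(pipeline = pipeline,
       out = dplyr::bind_cols(
         tibble(t2star_raw = t2, fit_ok = est$fit_ok,
                peak_freq_hz = est$peak_freq_hz,
                residual_rms = est$residual_rms),
         st$out[, c("detrended", "filtered", "spike", "feedback")]))
}

#' Process a whole session into a feedback log
#'
#' Streaming replay of [process_frame()] at one frame per repetition. The
#' first `n_discard` repetitions are estimated for diagnostics but never
#' enter the filter states; their chain columns are `NA`.
#'
#' @param session An `svps_session`.
#' @param filter An [svps_filter] (use the optimised regression length).
#' @param chain An [svps_chain].
#' @return An `svps_feedback` tibble, one row per repetition: `rep`,
#'   `label`, `discarded`, `t2star_raw`, `fit_ok`, `peak_freq_hz`,
#'   `residual_rms`, `detrended`, `filtered`, `spike`, `feedback`.
#' @export
process_session <- function(session, filter = svps_filter(),
                            chain = svps_chain()) {
  stopifnot(inherits(session, "svps_session"))
  design <- session$design
  series <- t2star_series(session, filter)
  retain <- retained_reps(design)
  cond <- process_series(series$t2star[retain], chain,
                         floor_ref = series$t2star[retain][1])
  n <- design$n_reps
  out <- tibble(rep = seq_len(n),
                label = design$labels,
                discarded = seq_len(n) <= design$n_discard,
                t2star_raw = series$t2star,
                fit_ok = series$fit_ok,
                peak_freq_hz = series$peak_freq_hz,
                residual_rms = series$residual_rms,
                detrended = NA_real_, filtered = NA_real_,
                spike = NA, feedback = NA_real_)
  out$detrended[retain] <- cond$detrended
  out$filtered[retain] <- cond$filtered
  out$spike[retain] <- cond$spike
  out$feedback[retain] <- cond$feedback
  class(out) <- c("svps_feedback", class(out))
  attr(out, "filter") <- filter
  attr(out, "chain") <- chain
  out
}

#' @export
autoplot.svps_feedback <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "rep", "label",
                  "t2star_raw", "detrended", "filtered", "feedback"),
    cols = c("t2star_raw", "detrended", "filtered", "feedback"),
    names_to = "stage", values_to = "value")
  long$stage <- factor(long$stage,
                       levels = c("t2star_raw", "detrended", "filtered",
                                  "feedback"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$rep, y = .data$value)) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::facet_wrap(~stage, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "repetition", y = NULL,
                  title = "Feedback signal conditioning stages") +
    ggplot2::theme_minimal()
}
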