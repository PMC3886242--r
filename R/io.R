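#' Write / read a simulated session on disk
#'
#' A session directory holds `frames.csv` (long format: `rep`, `sample`,
#' `time_s`, `real`, `imag`) and `truth.json` (design, acquisition,
#' generator parameters and the per-repetition ground truth). The pair is
#' sufficient to reconstruct the `svps_session` exactly (to the printed
#' precision of the CSV; `write_session()` uses full precision).
#'
#' @param session An `svps_session`.
#' @param dir Target directory (created if needed).
#' @return `write_session()`: the directory, invisibly. `read_session()`:
#'   the reconstructed `svps_session`.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "svps_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(session), file.path(dir, "frames.csv"))
  side <- list(
    design = unclass(session$design),
    acq = unclass(session$acq),
    truth = session$truth,
    params = list(bold = unclass(session$params$bold),
                  water = as.data.frame(session$params$water),
                  contaminants = as.data.frame(session$params$contaminants),
                  noise = unclass(session$params$noise),
                  seed = session$params$seed))
  jsonlite::write_json(side, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  frames_path <- file.path(dir, "frames.csv")
  truth_path <- file.path(dir, "truth.json")
  if (!file.exists(frames_path) || !file.exists(truth_path)) {
    svps_abort(sprintf("not a session directory: %s", dir),
               class = "svps_io_error")
  }
  frames <- readr::read_csv(frames_path, show_col_types = FALSE)
  side <- jsonlite::read_json(truth_path, simplifyVector = TRUE)

  design <- do.call(svps_design, side$design[c("tr", "block_len", "n_blocks",
                                               "n_discard")])
  acq <- do.call(svps_acquisition, side$acq[c("bandwidth", "n_points", "te")])
  n_pt <- acq$n_points
  n_rep <- design$n_reps
  if (nrow(frames) != n_pt * n_rep) {
    svps_abort("frames.csv is inconsistent with the recorded design",
               class = "svps_io_error")
  }
  frames <- dplyr::arrange(frames, .data$rep, .data$sample)
  fids <- matrix(complex(real = frames$real, imaginary = frames$imag),
                 nrow = n_pt, ncol = n_rep)
  noise_args <- side$params$noise
  noise_args$drift_phase <- noise_args$drift_phase %||% NULL
  structure(list(fids = fids,
                 truth = as_tibble(side$truth),
                 design = design, acq = acq,
                 params = list(bold = do.call(svps_bold, side$params$bold),
                               water = do.call(svps_components,
                                               side$params$water),
                               contaminants = if (NROW(side$params$contaminants) > 0)
                                 do.call(svps_components, side$params$contaminants)
                               else svps_water()[0, ],
                               noise = do.call(svps_noise, noise_args),
                               seed = side$params$seed)),
            class = "svps_session")
}

#' Write analysis outputs as flat files
#'
#' `write_t2_series()` stores a [t2star_series()] tibble, `write_tcurve()`
#' the optimisation curve, `write_feedback()` a [process_session()] log
#' (all CSV), and `write_metrics()` a [session_metrics()] row as JSON.
#'
#' @param x The object to write.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_t2_series <- function(x, path) {
  readr::write_csv(dplyr::select(x, "rep", t2star_s = "t2star", "amplitude",
                                 phase_rad = "phase", "residual_rms",
                                 "fit_ok"), path)
  invisible(path)
}

#' @rdname write_t2_series
#' @export
write_tcurve <- function(x, path) {
  stopifnot(inherits(x, "svps_lcurve"))
  readr::write_csv(x$t_curve, path)
  invisible(path)
}

#' @rdname write_t2_series
#' @export
write_feedback <- function(x, path) {
  stopifnot(inherits(x, "svps_feedback"))
  readr::write_csv(
    dplyr::select(as_tibble(x), "rep", "t2star_raw", "detrended",
                  "filtered", spike_flag = "spike",
                  feedback_norm = "feedback"),
    path)
  invisible(path)
}

#' @rdname write_t2_series
#' @export
write_metrics <- function(x, path) {
  jsonlite::write_json(as.list(x), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
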