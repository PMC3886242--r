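#' @export
autoplot.svps_session <- function(object, ...) {
  tr <- dplyr::mutate(object$truth,
                      t2_ms = 1000 * .data$realized_t2star,
                      true_ms = 1000 * .data$true_t2star)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$rep)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$t2_ms), colour = "grey55") +
    ggplot2::geom_line(ggplot2::aes(y = .data$true_ms), colour = "steelblue") +
    ggplot2::geom_point(data = dplyr::filter(tr, .data$spike),
                        ggplot2::aes(y = .data$t2_ms), colour = "red",
                        shape = 4) +
    ggplot2::labs(x = "repetition", y = "T2* (ms)",
                  title = "Simulated session ground truth",
                  subtitle = "blue: BOLD component; grey: realised (drift + spikes); x: spikes") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.svps_spectrum <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$magnitude)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "frequency (Hz)", y = "|S(f)|",
                  title = "Magnitude spectrum") +
    ggplot2::theme_minimal()
}
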