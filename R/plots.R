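# Optional report figures (connectivity histogram and FISH bubble plot).

#' Histogram of patient maximum connectivity values
#'
#' Distribution of per-patient maximum-spot connectivity; on real cohorts
#' this is typically bimodal with a heavy negative mode.
#'
#' @param connect_max Numeric vector of per-patient maximum connectivity
#'   values in \[0, 1\].
#' @param bins Number of bins (default 20).
#' @return A ggplot object.
#' @export
plot_connectivity_hist <- function(connect_max, bins = 20) {
  df <- data.frame(connect_max = connect_max)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$connect_max)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0, fill = "grey40") +
    ggplot2::labs(x = "maximum spot connectivity", y = "patients") +
    ggplot2::theme_classic()
}

#' Bubble plot of connectivity against FISH results
#'
#' Mean CEP17 per cell on the horizontal axis, mean HER2 per cell and the
#' HER2/CEP17 ratio as two bubbles per patient, bubble size proportional to
#' the patient's maximum connectivity. Dashed reference lines separate
#' polysomy (CEP17 > 3) and amplification (HER2 > 6, ratio > 2).
#'
#' @param patients Patient records with `fish_cep17`, `fish_her2`,
#'   `fish_ratio` and `connect_max`.
#' @return A ggplot object.
#' @export
plot_fish_bubble <- function(patients) {
  long <- rbind(
    data.frame(cep17 = patients$fish_cep17, value = patients$fish_her2,
               what = "mean HER2", connect_max = patients$connect_max),
    data.frame(cep17 = patients$fish_cep17, value = patients$fish_ratio,
               what = "HER2/CEP17 ratio", connect_max = patients$connect_max)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cep17, y = .data$value,
                                     size = .data$connect_max,
                                     color = .data$what)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 3, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 6, linetype = "dashed",
                        color = "steelblue") +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed",
                        color = "darkorange") +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(x = "mean CEP17 per cell", y = "mean HER2 / ratio",
                  size = "connect max", color = NULL) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 .data
NULL
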