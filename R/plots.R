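#' Plot a batch pixel-intensity histogram
#'
#' Bar plot of pixel counts per intensity on a log-friendly sqrt scale, with
#' the suggested background cut-off annotated. The flattening of this curve
#' is the visual cue for choosing the cut-off.
#'
#' @param hist Tibble from [batch_intensity_histogram()].
#' @param cutoff Optional intensity to annotate with a vertical line.
#' @return A ggplot object.
#' @export
plot_intensity_histogram <- function(hist, cutoff = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$intensity, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::labs(x = "pixel intensity", y = "pixel count",
                  title = "pixel_intensity") +
    ggplot2::theme_minimal()
  if (!is.null(cutoff)) {
    p <- p + ggplot2::geom_vline(xintercept = cutoff, color = "red",
                                 linetype = "dashed") +
      ggplot2::annotate("text", x = cutoff, y = Inf, vjust = 1.5, hjust = -0.1,
                        label = paste0("suggested cut-off = ", cutoff),
                        color = "red", size = 3)
  }
  p
}

#' Plot the marker (nucleus) size distribution
#'
#' @param sizes Tibble from [marker_size_histogram()].
#' @return A ggplot object.
#' @export
plot_marker_sizes <- function(sizes) {
  if (nrow(sizes) == 0) {
    sizes <- tibble(bin_low = 0, bin_high = 100, count = 0L)
  }
  ggplot2::ggplot(sizes,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = sizes$bin_high[1] - sizes$bin_low[1],
                      fill = "steelblue") +
    ggplot2::labs(x = "object area (px)", y = "objects", title = "MARKER_size") +
    ggplot2::theme_minimal()
}

save_plot <- function(p, path, width = 6, height = 4) {
  ggplot2::ggsave(path, plot = p, width = width, height = height, dpi = 120)
  path
}
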