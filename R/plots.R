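#' Plot an epitope panel along its target
#'
#' Draws the designed windows as segments along the target sequence,
#' coloured by complementarity score, with the masked region shaded.
#'
#' @param object An `epitope_panel`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epitope_panel <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(row = dplyr::row_number())
  mask <- attr(object, "mask")
  p <- ggplot2::ggplot(df)
  if (length(mask) > 0) {
    p <- p + ggplot2::annotate(
      "rect",
      xmin = min(mask) - 0.5, xmax = max(mask) + 0.5,
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "grey40"
    )
  }
  p +
    ggplot2::geom_segment(
      ggplot2::aes(
        x = .data$start, xend = .data$end,
        y = .data$row, yend = .data$row, colour = .data$c_score
      ),
      linewidth = 3, lineend = "round", na.rm = TRUE
    ) +
    ggplot2::geom_text(
      ggplot2::aes(
        x = (.data$start + .data$end) / 2, y = .data$row + 0.35,
        label = .data$label
      ),
      size = 3
    ) +
    ggplot2::scale_y_reverse(breaks = NULL) +
    ggplot2::labs(
      x = paste0("residue position (", attr(object, "target_id"), ")"),
      y = NULL, colour = "C score",
      title = "Designed epitope windows"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fragment library summary
#'
#' Shows the number of indexed observations per target-subsequence
#' length and orientation.
#'
#' @param object A `fragment_library`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fragment_library <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(length = nchar(.data$target_subseq)) |>
    group_by(.data$length, .data$orientation) |>
    summarise(observations = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = factor(.data$length), y = .data$observations,
      fill = .data$orientation
    )
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "target subsequence length", y = "observations",
      fill = "orientation", title = "Fragment library contents"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an intrinsic solubility profile
#'
#' Per-residue intrinsic values and the smoothed profile used by
#' [solubility_score()].
#'
#' @param seq Amino-acid sequence.
#' @param window Smoothing window width.
#' @return A ggplot object.
#' @export
plot_solubility_profile <- function(seq, window = 7L) {
  df <- solubility_profile(seq, window)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$intrinsic),
      fill = "grey70", width = 0.7
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$smoothed),
      colour = "steelblue", linewidth = 1
    ) +
    ggplot2::scale_x_continuous(
      breaks = df$position, labels = df$residue
    ) +
    ggplot2::labs(
      x = "residue", y = "intrinsic solubility",
      title = "Solubility profile (higher = more soluble)"
    ) +
    ggplot2::theme_minimal()
}
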