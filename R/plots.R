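#' Activation plot of a screen
#'
#' Strip plot of per-cell IFN-gamma UMI counts by condition for activated
#' cells, colored by V(D)J status, mirroring the per-cell activation
#' panels of a screen report.
#'
#' @param x A `tcr_screen` or `tcr_screen_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_activation <- function(x, ...) {
  activated <- if (inherits(x, "tcr_screen_result")) x$screen$activated
               else x$activated
  ggplot2::ggplot(activated,
                  ggplot2::aes(x = .data$condition, y = .data$ifng,
                               colour = .data$vdj_status)) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.8) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = NULL, y = "IFN-γ UMIs",
                  colour = "TCR status",
                  title = "Activated single cells per stimulation") +
    ggplot2::theme_minimal()
}

#' @rdname plot_activation
#' @param object A `tcr_screen` object.
#' @export
autoplot.tcr_screen <- function(object, ...) plot_activation(object, ...)

#' Clonotype frequency pie
#'
#' Pie chart of merged clonotype frequencies after singleton removal.
#' Clonotypes above the labelling threshold (default 1%) are colored
#' individually; candidate clonotypes can be highlighted.
#'
#' @param x A `tcr_frequency` table.
#' @param label_min Frequency above which a clonotype gets its own slice
#'   color.
#' @param highlight Optional clonotype keys (e.g. candidate keys) drawn
#'   with emphasis.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_frequencies <- function(x, label_min = 0.01, highlight = NULL, ...) {
  d <- as_tibble(x) |>
    mutate(slice = dplyr::case_when(
      .data$cdr3b_nt %in% highlight ~ "candidate",
      .data$frequency >= label_min ~ substr(.data$cdr3b_nt, 1, 9),
      TRUE ~ "other")) |>
    group_by(.data$slice) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    arrange(desc(.data$frequency))
  ggplot2::ggplot(d, ggplot2::aes(x = "", y = .data$frequency,
                                  fill = .data$slice)) +
    ggplot2::geom_col(width = 1, colour = "white", linewidth = 0.2) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(fill = "clonotype",
                  title = "Merged clonotype frequencies") +
    ggplot2::theme_void()
}

#' @rdname plot_frequencies
#' @param object A `tcr_frequency` table.
#' @export
autoplot.tcr_frequency <- function(object, ...) plot_frequencies(object, ...)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
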