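behaviour_palette <- function() {
  c(sleep = "#3b4cc0", SB = "#b0b0b0", LIPA = "#76b041", MVPA = "#d7301f")
}

#' Plot a minute-of-day behaviour profile
#'
#' Stacked-area chart of behaviour fractions over the 24-hour day.
#'
#' @param profile A [impute_profile()] result.
#' @return A ggplot object.
#' @export
plot_minute_profile <- function(profile) {
  long <- tidyr::pivot_longer(as_tibble(profile), dplyr::all_of(.BEHAVIOURS),
                              names_to = "behaviour", values_to = "fraction")
  long$behaviour <- factor(long$behaviour, levels = rev(.BEHAVIOURS))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$minute / 60, y = .data$fraction,
                                     fill = .data$behaviour)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_manual(values = behaviour_palette()) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4)) +
    ggplot2::labs(x = "Hour of day", y = "Fraction of days",
                  fill = "Behaviour") +
    ggplot2::theme_minimal()
}

#' @rdname plot_minute_profile
#' @param object A `minute_profile`.
#' @param ... Unused.
#' @method autoplot minute_profile
#' @export
autoplot.minute_profile <- function(object, ...) plot_minute_profile(object)

#' Plot time-reallocation hazard-ratio curves
#'
#' HR (with 95% CI ribbon) against minutes/day reallocated, one panel per
#' donor behaviour and one colour per recipient, anchored at the
#' reference composition (HR = 1 at 0 minutes).
#'
#' @param grid A [reallocation_grid()] result.
#' @return A ggplot object.
#' @export
plot_reallocation <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$amount_min, y = .data$hr,
                                     colour = .data$to, fill = .data$to)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low,
                                      ymax = .data$conf_high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~from, labeller = ggplot2::label_both) +
    ggplot2::scale_colour_manual(values = behaviour_palette()) +
    ggplot2::scale_fill_manual(values = behaviour_palette()) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Time reallocated (min/day)", y = "Hazard ratio",
                  colour = "To", fill = "To") +
    ggplot2::theme_minimal()
}

#' @rdname plot_reallocation
#' @param object A `realloc_grid`.
#' @param ... Unused.
#' @method autoplot realloc_grid
#' @export
autoplot.realloc_grid <- function(object, ...) plot_reallocation(object)

#' Plot a confusion matrix as a heat map
#'
#' @param confusion 4 x 4 matrix (counts or minutes), rows = truth.
#' @return A ggplot object.
#' @export
plot_confusion <- function(confusion) {
  df <- as.data.frame(as.table(confusion))
  names(df) <- c("truth", "predicted", "minutes")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$minutes)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$minutes))) +
    ggplot2::scale_fill_gradient(low = "white", high = "#3b4cc0") +
    ggplot2::scale_y_discrete(limits = rev(.BEHAVIOURS)) +
    ggplot2::labs(x = "Model-assigned", y = "Ground truth") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
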