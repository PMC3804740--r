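# ggplot2 visual summaries of the result tables (heatmap analogues of the
# plate viewers, and the object-based area distribution).

#' Plate heatmap of a well-level value
#'
#' The familiar screening heatmap: one tile per well, one facet per plate,
#' green-black-red fill (values increasing from green via black to red).
#'
#' @param wells Well tibble with `plate_id`, `row`, `col` and the value
#'   column.
#' @param value Column to plot (`"raw"`, `"poc"` or `"bscore"`).
#' @return A ggplot object.
#' @export
plot_plate_heatmap <- function(wells, value = "bscore") {
  stopifnot(value %in% names(wells))
  ggplot2::ggplot(
    wells,
    ggplot2::aes(x = .data$col, y = .data$row, fill = .data[[value]])
  ) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_y_discrete(limits = rev(plate_row_letters())) +
    ggplot2::scale_x_continuous(breaks = 1:12) +
    ggplot2::scale_fill_gradient2(low = "green4", mid = "black", high = "red2",
                                  midpoint = stats::median(wells[[value]], na.rm = TRUE)) +
    ggplot2::facet_wrap(~plate_id) +
    ggplot2::labs(x = NULL, y = NULL, fill = value) +
    ggplot2::theme_minimal()
}

#' Binned cytoplasm-area distribution
#'
#' Bar plot of the [bin_areas()] relative frequencies with the cumulative
#' distribution overlaid.
#'
#' @param bins A [bin_areas()] tibble.
#' @return A ggplot object.
#' @export
plot_area_bins <- function(bins) {
  ggplot2::ggplot(bins, ggplot2::aes(x = (.data$lower + .data$upper) / 2)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pct), fill = "steelblue",
                      width = (bins$upper[1] - bins$lower[1]) * 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$cum_pct), colour = "red3") +
    ggplot2::geom_point(ggplot2::aes(y = .data$cum_pct), colour = "red3") +
    ggplot2::labs(x = "cytoplasm area", y = "cells (%)") +
    ggplot2::theme_minimal()
}

#' Autoplot a rule model
#'
#' Shows each rule's feature, threshold and the spread-vs-rest vote margin,
#' a quick view of which features drive the phenotype discrimination.
#'
#' @param object A [train_rules()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rule_model <- function(object, ...) {
  td <- tidy(object)
  vote_cols <- setdiff(names(td), c("rule", "feature", "threshold", "side"))
  long <- tidyr::pivot_longer(td, dplyr::all_of(vote_cols),
                              names_to = "class", values_to = "vote")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$rule), y = .data$vote,
                                     fill = .data$class, alpha = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(gt = 1, le = 0.45)) +
    ggplot2::facet_wrap(~feature + threshold, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "rule", y = "vote weight") +
    ggplot2::theme_minimal()
}
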