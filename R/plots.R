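#' Plot the per-group distribution of error types
#'
#' Stacked-bar view of the insertion/substitution/deletion shares returned
#' by [error_distribution()].
#'
#' @param dist A tibble from [error_distribution()].
#' @return A ggplot object.
#' @export
plot_error_distribution <- function(dist) {
  long <- dplyr::bind_rows(
    tibble(group = dist$group, type = "insertions", pct = dist$insertion_pct),
    tibble(group = dist$group, type = "substitutions",
           pct = dist$substitution_pct),
    tibble(group = dist$group, type = "deletions", pct = dist$deletion_pct)
  )
  long$type <- factor(long$type,
                      levels = c("insertions", "substitutions", "deletions"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$pct,
                                     fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of total errors (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Boxplots of per-segment WER by speaker group
#'
#' @param wer_values Numeric WER percentages.
#' @param groups Group label per value (or `NULL`).
#' @return A ggplot object.
#' @export
plot_group_wer <- function(wer_values, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(wer_values))
  d <- tibble(wer = wer_values, group = as.character(groups))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wer, y = .data$group)) +
    ggplot2::geom_boxplot(outlier.colour = "firebrick") +
    ggplot2::labs(x = "WER (%)", y = NULL) +
    ggplot2::theme_minimal()
}
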