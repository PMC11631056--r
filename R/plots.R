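# ggplot2 views of score tables and alpha reports.

#' Plot distributions of numeric scores across a cohort
#'
#' Histograms of every numeric scoring option present in a wide score table
#' (one facet per option, free x scales). `NA` scores are dropped from the
#' plot (they stay in the table).
#'
#' @param wide A wide score tibble from [scores_wide()].
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distributions <- function(wide, bins = 20) {
  numeric_cols <- names(wide)[vapply(wide, is.numeric, logical(1))]
  numeric_cols <- setdiff(numeric_cols, "person_id")
  long <- wide |>
    dplyr::select(dplyr::all_of(c("person_id", numeric_cols))) |>
    tidyr::pivot_longer(-"person_id", names_to = "option", values_to = "score") |>
    dplyr::filter(!is.na(.data$score))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::facet_wrap(~option, scales = "free") +
    ggplot2::labs(x = "score", y = "participants") +
    ggplot2::theme_minimal()
}

#' Plot an internal-consistency report
#'
#' Bar chart of alpha-if-item-deleted with the overall alpha as a reference
#' line: bars above the line mark items whose removal would raise alpha.
#'
#' @param object An `sdoh_alpha` from [cronbach_alpha()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sdoh_alpha <- function(object, ...) {
  df <- object$item_stats
  ggplot2::ggplot(df, ggplot2::aes(x = .data$question_code,
                                   y = .data$alpha_if_deleted)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = 2,
                        colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      title = sprintf("%s: alpha = %.3f (n = %d)", object$construct,
                      object$alpha, object$n_complete),
      x = NULL, y = "alpha if item deleted"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
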