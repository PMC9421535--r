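#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_point
#'   geom_col scale_fill_viridis_c labs theme_minimal coord_polar facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Heatmap of a similarity matrix
#'
#' @param object an `airr_similarity` matrix.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.airr_similarity <- function(object, ...) {
  df <- tidy(object, upper_only = FALSE)
  diag_df <- tibble::tibble(from = rownames(object), to = rownames(object),
                            feature = attr(object, "feature"), similarity = 1)
  df <- dplyr::bind_rows(df, diag_df)
  ggplot(df, aes(x = .data$from, y = .data$to, fill = .data$similarity)) +
    geom_tile() +
    scale_fill_viridis_c(limits = c(0, 1)) +
    labs(title = sprintf("Similarity: %s", attr(object, "feature")),
         x = NULL, y = NULL, fill = "similarity") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Evenness profile curve
#'
#' @param object an `airr_evenness` profile.
#' @param ... unused.
#' @export
autoplot.airr_evenness <- function(object, ...) {
  ggplot(object, aes(x = .data$alpha, y = .data$evenness)) +
    geom_line() +
    ggplot2::ylim(0, 1) +
    labs(x = expression(alpha), y = "evenness") +
    theme_minimal()
}

#' Feature-sufficiency curve
#'
#' @param object an `airr_sufficiency` tibble.
#' @param ... unused.
#' @export
autoplot.airr_sufficiency <- function(object, ...) {
  ggplot(object, aes(x = .data$step, y = .data$mean_abs_change)) +
    geom_line() + geom_point() +
    labs(x = "features n (step n to n+1)",
         y = "mean |change| in composite similarity") +
    theme_minimal()
}

#' Local-similarity bar chart
#'
#' @param object an `airr_local` tibble.
#' @param ... unused.
#' @export
autoplot.airr_local <- function(object, ...) {
  ggplot(object, aes(x = stats::reorder(.data$id, .data$local),
                     y = .data$local)) +
    geom_col() +
    ggplot2::coord_flip() +
    labs(x = NULL, y = "local similarity") +
    theme_minimal()
}

#' Radar-style per-feature comparison plot
#'
#' Visualizes a [compare_to_reference()] table: one polygon per query over
#' the feature axes.
#'
#' @param comparison tibble from [compare_to_reference()].
#' @return a ggplot (polar coordinates).
#' @export
plot_feature_radar <- function(comparison) {
  long <- tidyr::pivot_longer(comparison,
                              cols = -dplyr::any_of(c("query", "reference",
                                                      "reference_cohort")),
                              names_to = "feature", values_to = "similarity")
  ggplot(long, aes(x = .data$feature, y = .data$similarity,
                   group = .data$query, colour = .data$query)) +
    geom_line() + geom_point() +
    coord_polar() +
    ggplot2::ylim(0, 1) +
    theme_minimal()
}
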