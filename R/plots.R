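#' Plot a bucketed rank summary
#'
#' Bar chart of the rank buckets (share of queries per bucket), the usual
#' way ranking benchmarks of candidate databases are reported.
#'
#' @param object A `rank_summary` or `benchmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_summary <- function(object, ...) {
  tot <- attr(object, "total")
  df <- as_tibble(object)
  df$fraction <- if (tot > 0) df$count / tot else 0
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bucket, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "rank bucket", y = "share of queries") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.rank_summary
#' @export
autoplot.benchmark_result <- function(object, ...) {
  autoplot(object$summary, ...)
}

#' Plot database content by annotation category
#'
#' Bar chart of entry (IKFB) counts per category, subcategories stacked
#' within their top category. Counts include the deliberate duplication of
#' entries annotated in several subcategories.
#'
#' @param summary Output of [category_summary()] (or a `lite_build`, which
#'   is summarised first).
#' @param idx Passed to [category_summary()] when needed.
#' @return A ggplot object.
#' @export
plot_category_summary <- function(summary, idx = NULL) {
  if (inherits(summary, "lite_build")) summary <- category_summary(summary, idx)
  tops <- summary[summary$sub_name == "", ]
  ggplot2::ggplot(tops, ggplot2::aes(
    x = stats::reorder(.data$short_name, .data$ikfb_count),
    y = .data$ikfb_count)) +
    ggplot2::geom_col(fill = "#41ab5d") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "entries (IKFB)") +
    ggplot2::theme_minimal()
}
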