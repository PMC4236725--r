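# ggplot2 views of the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the distribution of odds-ratio scores
#'
#' Histogram of per-TF odds ratios (finite scores only), the usual
#' first look at how strongly hotspot binding separates the roster.
#'
#' @param object Output of [odds_ratio()].
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_or_distribution <- function(object, bins = 30, ...) {
  df <- object[is.finite(object$odds_ratio), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey30") +
    ggplot2::labs(x = "odds ratio (hotspot vs coldspot binding)",
                  y = "TF count") +
    ggplot2::theme_minimal()
}

#' @rdname plot_or_distribution
#' @method autoplot or_table
#' @export
autoplot.or_table <- function(object, ...) plot_or_distribution(object, ...)

#' Plot a random-walk fit
#'
#' Steady-state relevance of the top-ranked nodes, seeds highlighted.
#'
#' @param object An `rwr_fit`.
#' @param top_n Number of nodes shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rwr_fit
#' @export
autoplot.rwr_fit <- function(object, top_n = 25, ...) {
  df <- utils::head(tidy(object), top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$gene_id, .data$p),
    y = .data$p, fill = .data$is_seed)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "steady-state relevance p",
                  fill = "seed") +
    ggplot2::theme_minimal()
}

#' Plot gap scores of ranked GO terms
#'
#' @param object Output of [rank_terms_by_gap()].
#' @param top_n Number of terms shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_gap_scores <- function(object, top_n = 10, ...) {
  df <- utils::head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$term, .data$gap), y = .data$gap)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gap score") +
    ggplot2::theme_minimal()
}
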