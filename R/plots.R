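#' @importFrom ggplot2 ggplot aes geom_col geom_histogram labs facet_wrap
#'   autoplot scale_y_continuous position_dodge theme_minimal
NULL

#' @export
ggplot2::autoplot

#' Plot per-path site-class composition
#'
#' Stacked bars of STABLE/UP/DOWN/OTHER counts for each differentiation
#' path, the standard summary of how chromatin accessibility changes along
#' each lineage.
#'
#' @param object An `acc_class` from [classify_sites()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.acc_class <- function(object, ...) {
  ggplot(object$tally, aes(x = .data$path, y = .data$n_sites,
                           fill = .data$class)) +
    geom_col() +
    labs(x = "differentiation path", y = "sites", fill = "class",
         title = "Site classification by lineage") +
    theme_minimal()
}

#' Plot sensitivity and specificity per progenitor
#'
#' Side-by-side bars of sensitivity and specificity for each internal node
#' compared with its observed progenitor profile.
#'
#' @param confusion Tibble from [evaluate_progenitors()] (optionally
#'   row-bound over methods with a `method` column).
#' @return A ggplot object.
#' @export
plot_confusion <- function(confusion) {
  long <- confusion |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "measure", values_to = "value")
  p <- ggplot(long, aes(x = .data$node, y = .data$value,
                        fill = .data$measure)) +
    geom_col(position = position_dodge()) +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = "progenitor node", y = NULL,
         title = "Predicted progenitor chromatin states") +
    theme_minimal()
  if ("method" %in% names(confusion)) p <- p + facet_wrap(~method)
  p
}

#' Plot the quartet delta distribution
#'
#' Histogram of per-quartet delta values (0 = perfectly treelike,
#' 1 = maximal conflict), optionally faceted by a `group` column.
#'
#' @param deltas Tibble from [delta_scores()], optionally row-bound over
#'   groups with a `group` column.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_delta <- function(deltas, bins = 20) {
  p <- ggplot(deltas, aes(x = .data$delta)) +
    geom_histogram(bins = bins, boundary = 0) +
    labs(x = expression(delta), y = "quartets",
         title = "Treelikeness (delta plot)") +
    theme_minimal()
  if ("group" %in% names(deltas)) p <- p + facet_wrap(~group)
  p
}
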