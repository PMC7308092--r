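# ggplot2 result graphics. Each result type gets an autoplot() method so
# figures chain naturally off the tidy outputs.

#' @importFrom rlang .data
NULL

#' Fold-score distributions per model
#'
#' @param object A `fold_scores` tibble (possibly several models bound
#'   together).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fold_scores <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$model, .data$mae)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = NULL, y = "MAE (years)")
}

#' Manhattan-style plot of delta--score associations
#'
#' `-log10(p)` per score, colored by deconfounding specification, with the
#' conventional 5%, 1% and 0.1% reference levels drawn as solid, dashed
#' and dotted lines.
#'
#' @param object A [delta_association_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.delta_association_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$score, -log10(.data$p_value),
                               color = .data$spec)) +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.1),
                        size = 2) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "solid") +
    ggplot2::geom_hline(yintercept = -log10(0.01), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(0.001), linetype = "dotted") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)), color = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Partial-dependence curve or surface
#'
#' @param object A [partial_dependence()] result.
#' @param ... Unused.
#' @return A ggplot (line for one feature, tile surface for two).
#' @export
autoplot.partial_dependence <- function(object, ...) {
  vars <- setdiff(names(object), "estimate")
  if (length(vars) == 1L) {
    ggplot2::ggplot(object, ggplot2::aes(.data[[vars[1L]]],
                                         .data$estimate)) +
      ggplot2::geom_line() +
      ggplot2::labs(y = "partial dependence (years)")
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data[[vars[1L]]],
                                         .data[[vars[2L]]],
                                         fill = .data$estimate)) +
      ggplot2::geom_tile() +
      ggplot2::labs(fill = "years")
  }
}

#' Variable-importance bars
#'
#' @param x An importance tibble (`feature`, `importance`, optionally
#'   `sd`), e.g. from [permutation_importance()] or [mdi_importance()].
#' @return A ggplot.
#' @export
plot_importance <- function(x) {
  x$feature <- stats::reorder(x$feature, x$importance)
  p <- ggplot2::ggplot(x, ggplot2::aes(.data$importance, .data$feature)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "importance", y = NULL)
  if ("sd" %in% names(x) && !all(is.na(x$sd))) {
    p <- p + ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$importance - .data$sd,
                   xmax = .data$importance + .data$sd), height = 0.2)
  }
  p
}
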