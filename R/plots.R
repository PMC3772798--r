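# ggplot2 visualisations for the package's result types.

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot pooled cross-validation scores as a ROC curve
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_result <- function(object, ...) {
  autoplot(roc_auc(object$scores$score, object$scores$label)) +
    ggplot2::labs(subtitle = sprintf("%d-fold CV, pooled held-out scores",
                                     object$n_folds))
}

#' Heatmap of a quantitative matrix
#'
#' Residue-by-position cell values; most readable for `mono` matrices.
#'
#' @param object A `quant_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.quant_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                   y = factor(.data$element,
                                              levels = rev(rownames(object$cells))),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = "Position (from N-terminus)", y = NULL,
                  fill = "pos - neg (%)",
                  title = sprintf("Quantitative matrix (%s)", object$mode)) +
    ggplot2::theme_minimal()
}

#' Between-class composition difference plot
#'
#' @param object A [composition_comparison()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.composition_comparison <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$residue, y = .data$difference,
                                       fill = .data$dominance)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(positive = "#B2182B",
                                          negative = "#2166AC",
                                          none = "grey70")) +
    ggplot2::labs(x = NULL, y = "Mean composition difference (pos - neg, %)",
                  title = "Per-residue composition comparison") +
    ggplot2::theme_minimal()
}

#' Per-position score track of a protein scan
#'
#' @param object A [scan_protein()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protein_scan <- function(object, ...) {
  track <- position_track(object)
  df <- tibble(position = seq_along(track), score = track)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line(colour = "#2166AC") +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dashed", colour = "#B2182B") +
    ggplot2::labs(x = "Protein position", y = "Max window score",
                  title = sprintf("Sliding-window scan (window = %d)",
                                  attr(object, "window"))) +
    ggplot2::theme_minimal()
}

#' Per-position extreme scores of a quantitative matrix
#'
#' Shows the maximum- and minimum-scoring element at every position as a
#' ribbon of the attainable score range.
#'
#' @param qm A `quant_matrix`.
#' @return A ggplot object.
#' @export
plot_position_extremes <- function(qm) {
  ex <- position_extremes(qm)
  ggplot2::ggplot(ex, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$min_score,
                                      ymax = .data$max_score),
                         fill = "grey85") +
    ggplot2::geom_line(ggplot2::aes(y = .data$max_score), colour = "#B2182B") +
    ggplot2::geom_line(ggplot2::aes(y = .data$min_score), colour = "#2166AC") +
    ggplot2::geom_text(ggplot2::aes(y = .data$max_score,
                                    label = .data$max_element),
                       vjust = -0.4, size = 2.6) +
    ggplot2::labs(x = "Position (from N-terminus)", y = "Cell score",
                  title = "Maximum and minimum scoring elements per position") +
    ggplot2::theme_minimal()
}
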