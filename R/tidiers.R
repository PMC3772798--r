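# broom-style tidiers for the package's result objects.

#' Tidy a quantitative matrix into long format
#'
#' @param x A `quant_matrix`.
#' @param ... Unused.
#' @return Tibble with `element`, `position`, `value`.
#' @export
tidy.quant_matrix <- function(x, ...) {
  out <- as_tibble(x$cells, rownames = "element")
  out <- tidyr::pivot_longer(out, -"element", names_to = "position",
                             values_to = "value")
  out$position <- as.integer(sub("^P", "", out$position))
  out
}

#' One-row summary of a quantitative matrix
#'
#' @param x A `quant_matrix`.
#' @param ... Unused.
#' @return One-row tibble: `mode`, `max_len`, `n_pos`, `n_neg`, `min_cell`,
#'   `max_cell`.
#' @export
glance.quant_matrix <- function(x, ...) {
  tibble(mode = x$mode, max_len = x$max_len, n_pos = x$n_pos, n_neg = x$n_neg,
         min_cell = min(x$cells), max_cell = max(x$cells))
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Tibble of `metric`, `value`.
#' @export
tidy.eval_report <- function(x, ...) {
  tibble(metric = c("sensitivity", "specificity", "accuracy", "mcc", "auc",
                    "threshold"),
         value = c(x$sensitivity, x$specificity, x$accuracy, x$mcc, x$auc,
                   x$threshold))
}

#' One-row summary of an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return One-row tibble mirroring the conventional reporting column order.
#' @export
glance.eval_report <- function(x, ...) {
  tibble(threshold = x$threshold, sensitivity = x$sensitivity,
         specificity = x$specificity, accuracy = x$accuracy, mcc = x$mcc,
         auc = x$auc, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn)
}

#' Per-fold metrics of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per fold plus the fold index.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$folds), function(f) {
    dplyr::bind_cols(tibble(fold = f), glance(x$folds[[f]]))
  }))
}

#' Pooled summary of a cross-validation run
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble of the pooled report plus `n_folds`, `seed`,
#'   `hybrid`.
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(glance(x$report),
                   tibble(n_folds = x$n_folds, seed = x$seed, hybrid = x$hybrid))
}

#' One-row summary of a trained model
#'
#' @param x A `toxin_model`.
#' @param ... Unused.
#' @return One-row tibble: scheme, kernel, hyperparameters, class sizes,
#'   number of support vectors.
#' @export
glance.toxin_model <- function(x, ...) {
  tibble(scheme = x$config$scheme, kernel = x$config$kernel,
         gamma = x$config$gamma, cost = x$config$cost,
         pos_class_weight = x$config$pos_class_weight,
         threshold = x$config$threshold, n_pos = x$meta$n_pos,
         n_neg = x$meta$n_neg, n_support = x$fit$tot.nSV, seed = x$meta$seed)
}

#' Tidy a motif set
#'
#' @param x A `motif_set`.
#' @param ... Unused.
#' @return Tibble with one row per motif: `id`, `consensus`, `width`,
#'   `enrichment`, `n_sites`, `n_pos`, `n_neg`.
#' @export
tidy.motif_set <- function(x, ...) {
  dplyr::bind_rows(lapply(x, function(m) {
    tibble(id = m$id, consensus = m$consensus, width = m$width,
           enrichment = m$enrichment, n_sites = m$n_sites,
           n_pos = m$n_pos, n_neg = m$n_neg)
  }))
}
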