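# Cross-validation, threshold calibration and the standard performance
# statistics: sensitivity, specificity, accuracy, Matthews correlation
# coefficient, ROC/AUC, and precision/coverage for abstaining predictors.

#' Confusion counts from calls and labels
#'
#' @param pred Character vector of `"toxic"` / `"nontoxic"` calls.
#' @param truth Character vector of true labels, same values.
#' @return Named list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    .stop_domain("pred and truth must be non-empty vectors of equal length")
  }
  list(tp = sum(pred == "toxic" & truth == "toxic"),
       fp = sum(pred == "toxic" & truth == "nontoxic"),
       tn = sum(pred == "nontoxic" & truth == "nontoxic"),
       fn = sum(pred == "nontoxic" & truth == "toxic"))
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `= 100 tp / (tp + fn)`, specificity `= 100 tn / (tn + fp)`,
#' accuracy `= 100 (tp + tn) / total`, and Matthews correlation coefficient
#' `MCC = (tp tn - fp fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, with the
#' standard convention MCC = 0 when any denominator factor is zero.
#'
#' @param counts A list/row with `tp`, `fp`, `tn`, `fn` (as from
#'   [confusion_counts()]).
#' @param auc Optional AUC to carry in the report.
#' @param threshold Optional threshold to carry in the report.
#' @return An object of class `eval_report`.
#' @export
eval_metrics <- function(counts, auc = NA_real_, threshold = NA_real_) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  if (any(is.na(c(tp, fp, tn, fn))) || any(c(tp, fp, tn, fn) < 0)) {
    .stop_domain("counts must be non-negative tp, fp, tn, fn")
  }
  total <- tp + fp + tn + fn
  if (total == 0) .stop_domain("no evaluated records (total count is zero)")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / total,
    mcc = mcc, auc = auc, threshold = threshold),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n=%d  threshold=%s\n  Sensitivity %.2f  Specificity %.2f  Accuracy %.2f  MCC %.3f  AUC %s\n",
    as.integer(x$tp + x$fp + x$tn + x$fn),
    if (is.na(x$threshold)) "NA" else format(x$threshold),
    x$sensitivity, x$specificity, x$accuracy, x$mcc,
    if (is.na(x$auc)) "NA" else sprintf("%.3f", x$auc)))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps every distinct score as a threshold (call toxic when
#' `score >= threshold`), grouping tied scores into a single step, and
#' integrates by the trapezoid rule. This tie handling makes the AUC equal to
#' the Mann-Whitney probability with ties counted 1/2.
#'
#' @param scores Numeric decision scores (larger = more toxic-like).
#' @param labels `"toxic"` / `"nontoxic"` labels; both classes must be
#'   present.
#' @return An object of class `roc_result`: `auc` plus a `points` tibble of
#'   `threshold`, `fpr`, `tpr`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels)) .stop_domain("scores/labels length mismatch")
  is_pos <- labels == "toxic"
  if (!any(is_pos) || all(is_pos)) {
    .stop_domain("ROC needs both classes present in labels")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[is_pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!is_pos] >= t), numeric(1))
  tpr <- c(0, tpr); fpr <- c(0, fpr); thr <- c(Inf, thr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(auc = auc,
                 points = tibble(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f over %d threshold steps\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' Select a decision threshold by accuracy sweep
#'
#' Sweeps thresholds from `min(scores)` to `max(scores)` at the grid step and
#' returns the one maximizing accuracy (call toxic when
#' `score >= threshold`). Ties are broken by the smallest
#' `|sensitivity - specificity|`, then by the lower threshold. When all scores
#' are identical the (degenerate) common value is returned with a warning.
#'
#' @inheritParams roc_auc
#' @param step Grid step (default 0.1).
#' @return The selected threshold, with attributes `accuracy`, `sensitivity`,
#'   `specificity`.
#' @export
threshold_select <- function(scores, labels, step = 0.1) {
  is_pos <- labels == "toxic"
  if (!any(is_pos) || all(is_pos)) {
    .stop_domain("threshold selection needs both classes present")
  }
  lo <- min(scores); hi <- max(scores)
  if (lo == hi) {
    warn("all scores identical; threshold selection is degenerate")
    grid <- lo
  } else {
    grid <- unique(c(seq(lo, hi, by = step), hi))
  }
  np <- sum(is_pos); nn <- sum(!is_pos)
  stats <- vapply(grid, function(t) {
    tp <- sum(scores[is_pos] >= t); tn <- sum(scores[!is_pos] < t)
    c(acc = 100 * (tp + tn) / (np + nn),
      sens = 100 * tp / np, spec = 100 * tn / nn)
  }, numeric(3))
  best_acc <- max(stats["acc", ])
  cand <- which(stats["acc", ] >= best_acc - 1e-12)
  bal <- abs(stats["sens", cand] - stats["spec", cand])
  cand <- cand[bal <= min(bal) + 1e-12]
  pick <- cand[1]   # grid ascending, so first = lowest threshold
  structure(grid[pick], accuracy = unname(stats["acc", pick]),
            sensitivity = unname(stats["sens", pick]),
            specificity = unname(stats["spec", pick]))
}

#' Stratified k-fold cross-validation
#'
#' Splits each class into `n_folds` random folds (the seed fixes the
#' partition), trains on `n_folds - 1` folds and scores the held-out fold.
#' One decision threshold is selected by [threshold_select()] on the pooled
#' held-out scores and applied to them for the pooled report; per-fold
#' reports use the same threshold. This mirrors how per-model thresholds are
#' conventionally reported alongside cross-validated performance; because the
#' SVM separates its own training records with a wide margin, tuning on
#' resubstitution scores would park the threshold at the margin edge instead
#' (see the methods vignette). Fix `threshold` to bypass tuning. When a
#' `motif_set` is supplied every score receives the hybrid motif boost before
#' thresholding.
#'
#' @param pos,neg Dataset tibbles for the toxic / non-toxic classes; each
#'   class must have at least `n_folds` encodable records.
#' @param config A [model_config()].
#' @param n_folds Number of folds (the conventional choices are 5 and 10).
#' @param seed Integer seed fixing the fold partition.
#' @param motifs Optional `motif_set` enabling hybrid scoring.
#' @param evalue_max E-value cutoff for hybrid motif hits (default 0.01; see
#'   the package vignette for why the hybrid default is stricter than the
#'   exploratory [scan_motifs()] default).
#' @param boost Hybrid score increment on a motif hit.
#' @param threshold Fix the threshold instead of tuning it.
#' @param step Grid step passed to [threshold_select()].
#' @return An object of class `cv_result`: `report` (pooled `eval_report`
#'   with AUC), `folds` (list of per-fold `eval_report`s), `scores` (tibble
#'   of `id`, `label`, `fold`, `score`, `call`), `threshold`, `config`,
#'   `n_folds`, `seed`, `hybrid`.
#' @export
kfold_cv <- function(pos, neg, config = model_config(), n_folds = 5L,
                     seed = 1L, motifs = NULL, evalue_max = 0.01, boost = 5,
                     threshold = NULL, step = 0.1) {
  .check_dataset(pos, "pos")
  .check_dataset(neg, "neg")
  dp <- .drop_unencodable(pos, config$scheme, "positive")
  dn <- .drop_unencodable(neg, config$scheme, "negative")
  pos <- dp$kept; neg <- dn$kept
  if (nrow(pos) < n_folds || nrow(neg) < n_folds) {
    .stop_domain(sprintf("each class needs >= %d records for %d-fold CV",
                         n_folds, n_folds))
  }
  set.seed(seed)
  fold_p <- sample(rep_len(seq_len(n_folds), nrow(pos)))
  fold_n <- sample(rep_len(seq_len(n_folds), nrow(neg)))

  hit_p <- rep(FALSE, nrow(pos)); hit_n <- rep(FALSE, nrow(neg))
  if (!is.null(motifs)) {
    hit_p <- motif_only_predict(pos, motifs, evalue_max)$call == "toxic"
    hit_n <- motif_only_predict(neg, motifs, evalue_max)$call == "toxic"
  }

  te_score <- numeric(0); te_label <- character(0)
  te_id <- character(0); te_fold <- integer(0)
  for (f in seq_len(n_folds)) {
    fit <- train_model(pos[fold_p != f, ], neg[fold_n != f, ], config, seed)
    s_te <- c(hybrid_score(decision_score(fit, pos[fold_p == f, ]),
                           hit_p[fold_p == f], boost),
              hybrid_score(decision_score(fit, neg[fold_n == f, ]),
                           hit_n[fold_n == f], boost))
    te_score <- c(te_score, s_te)
    te_label <- c(te_label, rep("toxic", sum(fold_p == f)),
                  rep("nontoxic", sum(fold_n == f)))
    te_id <- c(te_id, pos$id[fold_p == f], neg$id[fold_n == f])
    te_fold <- c(te_fold, rep.int(f, sum(fold_p == f) + sum(fold_n == f)))
  }

  if (is.null(threshold)) threshold <- threshold_select(te_score, te_label, step)
  threshold <- as.numeric(threshold)
  call <- ifelse(te_score >= threshold, "toxic", "nontoxic")
  pooled <- eval_metrics(confusion_counts(call, te_label),
                         auc = roc_auc(te_score, te_label)$auc,
                         threshold = threshold)
  folds <- lapply(seq_len(n_folds), function(f) {
    sel <- te_fold == f
    eval_metrics(confusion_counts(call[sel], te_label[sel]),
                 auc = tryCatch(roc_auc(te_score[sel], te_label[sel])$auc,
                                error = function(e) NA_real_),
                 threshold = threshold)
  })
  structure(list(
    report = pooled, folds = folds,
    scores = tibble(id = te_id, label = te_label, fold = te_fold,
                    score = te_score, call = call),
    threshold = threshold, config = config, n_folds = as.integer(n_folds),
    seed = as.integer(seed), hybrid = !is.null(motifs)),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold stratified CV (seed %d%s)\n",
              x$n_folds, x$seed, if (x$hybrid) ", hybrid motif boost" else ""))
  print(x$report)
  invisible(x)
}

#' Probability of correct prediction and coverage for abstaining predictors
#'
#' Coverage is the percent of records receiving any call; PCP is the percent
#' correct among the non-abstaining calls (missing when nothing is decided).
#'
#' @param calls Character vector of `"toxic"` / `"nontoxic"` / `"abstain"`.
#' @param labels True `"toxic"` / `"nontoxic"` labels.
#' @return One-row tibble: `pcp`, `coverage`, `n_decided`, `n_total`.
#' @export
pcp_coverage <- function(calls, labels) {
  if (length(calls) != length(labels)) .stop_domain("calls/labels length mismatch")
  decided <- calls != "abstain"
  tibble(
    pcp = if (any(decided)) 100 * mean(calls[decided] == labels[decided]) else NA_real_,
    coverage = if (length(calls)) 100 * mean(decided) else NA_real_,
    n_decided = sum(decided), n_total = length(calls))
}

#' Write an evaluation report to TSV
#'
#' Columns follow the conventional order Threshold, Sensitivity, Specificity,
#' Accuracy, MCC, AUC, preceded by `#` metadata lines.
#'
#' @param report An `eval_report` or `cv_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  meta <- character(0)
  if (inherits(report, "cv_result")) {
    meta <- c(sprintf("# n_folds=%d seed=%d hybrid=%s scheme=%s",
                      report$n_folds, report$seed, report$hybrid,
                      report$config$scheme))
    report <- report$report
  }
  stopifnot(inherits(report, "eval_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# eval_report", meta,
               sprintf("# tp=%d fp=%d tn=%d fn=%d",
                       as.integer(report$tp), as.integer(report$fp),
                       as.integer(report$tn), as.integer(report$fn))), con)
  df <- data.frame(Threshold = report$threshold,
                   Sensitivity = report$sensitivity,
                   Specificity = report$specificity,
                   Accuracy = report$accuracy,
                   MCC = report$mcc, AUC = report$auc)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
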