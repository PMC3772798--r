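test_that("metrics follow the standard confusion-count formulas", {
  perfect <- eval_metrics(list(tp = 50, fp = 0, tn = 50, fn = 0))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$mcc, 1)

  r <- eval_metrics(list(tp = 45, fp = 5, tn = 45, fn = 5))
  expect_equal(r$accuracy, 90)
  expect_equal(r$mcc, 0.8)   # (2025 - 25) / 2500
  expect_equal(r$sensitivity, 90)
  expect_equal(r$specificity, 90)

  # all calls toxic: a zero denominator factor gives MCC 0 by convention
  degenerate <- eval_metrics(list(tp = 10, fp = 10, tn = 0, fn = 0))
  expect_equal(degenerate$mcc, 0)
  # perfectly anti-correlated calls
  expect_equal(eval_metrics(list(tp = 0, fp = 10, tn = 0, fn = 10))$accuracy, 0)
  expect_error(eval_metrics(list(tp = 0, fp = 0, tn = 0, fn = 0)),
               class = "peptox_domain_error")
})

test_that("metrics agree with brute-force recounting on random prediction sets", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(5:60, 1)
    pred <- sample(c("toxic", "nontoxic"), n, replace = TRUE)
    truth <- sample(c("toxic", "nontoxic"), n, replace = TRUE)
    r <- eval_metrics(confusion_counts(pred, truth))
    expect_equal(r$accuracy, 100 * mean(pred == truth), tolerance = 1e-9)
    tp <- sum(pred == "toxic" & truth == "toxic")
    fn <- sum(pred == "nontoxic" & truth == "toxic")
    if (tp + fn > 0) {
      expect_equal(r$sensitivity, 100 * tp / (tp + fn), tolerance = 1e-9)
    }
  }
})

test_that("the ROC sweep matches an independent AUC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  for (i in 1:20) {
    n <- sample(c(30, 101, 400), 1)
    labels <- sample(c("toxic", "nontoxic"), n, replace = TRUE,
                     prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(n) + (labels == "toxic") * runif(1, 0, 2)
    if (i %% 3 == 0) scores <- round(scores, 1)   # force ties
    mine <- roc_auc(scores, labels)$auc
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(labels, scores, levels = c("nontoxic", "toxic"),
                          direction = "<"))))
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("ROC endpoints, reflection and monotone-transform invariance hold", {
  sep <- roc_auc(c(1, 2, 3, -1, -2), c(rep("toxic", 3), rep("nontoxic", 2)))
  expect_equal(sep$auc, 1)
  set.seed(43)
  scores <- rnorm(60)
  labels <- sample(c("toxic", "nontoxic"), 60, replace = TRUE)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(-scores, labels)$auc, 1 - a, tolerance = 1e-12)
  expect_equal(roc_auc(exp(scores), labels)$auc, a, tolerance = 1e-12)
  expect_error(roc_auc(scores, rep("toxic", 60)), class = "peptox_domain_error")
})

test_that("random scores give chance-level AUC at large n", {
  set.seed(44)
  scores <- rnorm(2000)
  labels <- sample(rep(c("toxic", "nontoxic"), 1000))
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 0.05)
})

test_that("threshold selection maximizes accuracy with the balanced-lowest tie-break", {
  th <- threshold_select(c(-1, -1, 1, 1),
                         c("nontoxic", "nontoxic", "toxic", "toxic"))
  expect_equal(as.numeric(th), -0.9)
  expect_equal(attr(th, "accuracy"), 100)

  # overlapping scores: coarse grid lands within one step of a fine sweep
  set.seed(45)
  scores <- c(rnorm(150, 1), rnorm(150, -1))
  labels <- c(rep("toxic", 150), rep("nontoxic", 150))
  coarse <- as.numeric(threshold_select(scores, labels, step = 0.1))
  fine <- as.numeric(threshold_select(scores, labels, step = 0.01))
  acc_at <- function(t) 100 * mean((scores >= t) == (labels == "toxic"))
  expect_lte(acc_at(fine) - acc_at(coarse), 1.0)
  expect_warning(deg <- threshold_select(c(2, 2, 2), c("toxic", "nontoxic", "toxic")),
                 "degenerate")
  expect_equal(as.numeric(deg), 2)
})

test_that("stratified CV is reproducible and conserves counts across folds", {
  sim <- sim_medium(60, seed = 8)
  cv1 <- kfold_cv(sim$pos, sim$neg, model_config("AAC"), n_folds = 5, seed = 11)
  cv2 <- kfold_cv(sim$pos, sim$neg, model_config("AAC"), n_folds = 5, seed = 11)
  expect_equal(cv1$scores, cv2$scores)
  expect_equal(cv1$threshold, cv2$threshold)

  # stratification: each fold holds n/n_folds records of each class
  per_fold <- table(cv1$scores$fold, cv1$scores$label)
  expect_true(all(per_fold == 12))
  # pooled counts equal the sum of per-fold counts
  fold_counts <- sapply(cv1$folds, function(f) c(f$tp, f$fp, f$tn, f$fn))
  expect_equal(unname(rowSums(fold_counts)),
               c(cv1$report$tp, cv1$report$fp, cv1$report$tn, cv1$report$fn))
  expect_error(kfold_cv(sim$pos[1:3, ], sim$neg, model_config("AAC"),
                        n_folds = 5, seed = 1),
               class = "peptox_domain_error")
})

test_that("the CV pipeline handles unbalanced class ratios unchanged", {
  sim <- generate_dataset(generator_config(n_pos = 30, n_neg = 210, seed = 9))
  cv <- kfold_cv(sim$pos, sim$neg, model_config("AAC"), n_folds = 5, seed = 1)
  expect_equal(cv$report$tp + cv$report$fn, 30)
  expect_equal(cv$report$tn + cv$report$fp, 210)
  expect_gt(cv$report$auc, 0.9)
})

test_that("PCP and coverage summarize abstaining predictors", {
  all_in <- pcp_coverage(c("toxic", "nontoxic"), c("toxic", "nontoxic"))
  expect_equal(all_in$pcp, 100)
  expect_equal(all_in$coverage, 100)
  half <- pcp_coverage(c("toxic", "abstain", "toxic", "abstain"),
                       c("toxic", "toxic", "toxic", "nontoxic"))
  expect_equal(half$pcp, 100)
  expect_equal(half$coverage, 50)
  none <- pcp_coverage(rep("abstain", 3), rep("toxic", 3))
  expect_true(is.na(none$pcp))
  expect_equal(none$coverage, 0)
})

test_that("evaluation reports serialize in the conventional column order", {
  r <- eval_metrics(list(tp = 45, fp = 5, tn = 45, fn = 5), auc = 0.95,
                    threshold = -0.4)
  path <- tempfile(fileext = ".tsv")
  withr::defer(unlink(path))
  write_eval_report(r, path)
  lines <- readLines(path)
  header <- lines[!grepl("^#", lines)][1]
  expect_equal(header,
               "Threshold\tSensitivity\tSpecificity\tAccuracy\tMCC\tAUC")
})

test_that("tidiers expose per-fold and pooled views of a CV run", {
  sim <- sim_medium(50, seed = 8)
  cv <- kfold_cv(sim$pos, sim$neg, model_config("AAC"), n_folds = 5, seed = 2)
  td <- tidy(cv)
  expect_equal(nrow(td), 5L)
  gl <- glance(cv)
  expect_equal(gl$accuracy, cv$report$accuracy)
  expect_equal(gl$n_folds, 5L)
})
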