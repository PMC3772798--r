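# SVM classification harness: encoding, label convention (toxic = +1 side),
# per-class cost weighting, decision-value scoring, thresholding, the hybrid
# motif-boost rule, and model persistence. The margin optimizer itself is
# libsvm via e1071::svm.

#' Model configuration
#'
#' Hyperparameters mirror the conventional SVM-light style naming: kernel
#' (`t`), `gamma` (`g`), `cost` (`c`), positive-class cost factor (`j`), and a
#' decision threshold on the raw decision-value scale. The default mirrors the
#' headline dipeptide-composition model: RBF kernel, gamma 0.001, cost 5,
#' balanced class cost, threshold -0.4. Absolute thresholds do not transfer
#' across SVM implementations, so cross-validation re-tunes the threshold by
#' default (see [kfold_cv()]); the configured value is used when no tuning is
#' requested.
#'
#' @param scheme Feature scheme name (see [scheme_min_length()]).
#' @param kernel `"rbf"`, `"linear"` or `"poly"`.
#' @param gamma RBF / polynomial kernel width parameter (> 0).
#' @param cost Soft-margin cost parameter C (> 0).
#' @param pos_class_weight Cost multiplier for the toxic class (> 0); the
#'   `j` parameter.
#' @param threshold Decision threshold: scores `>=` threshold are toxic.
#' @param degree Polynomial degree (poly kernel only).
#' @return An object of class `model_config`.
#' @export
model_config <- function(scheme = "DPC", kernel = c("rbf", "linear", "poly"),
                         gamma = 0.001, cost = 5, pos_class_weight = 1,
                         threshold = -0.4, degree = 3L) {
  kernel <- match.arg(kernel)
  if (gamma <= 0 || cost <= 0 || pos_class_weight <= 0) {
    .stop_domain("gamma, cost and pos_class_weight must all be positive")
  }
  .parse_scheme(scheme)
  structure(list(scheme = toupper(scheme), kernel = kernel, gamma = gamma,
                 cost = cost, pos_class_weight = pos_class_weight,
                 threshold = threshold, degree = as.integer(degree)),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> scheme=%s kernel=%s g=%g c=%g j=%g threshold=%g\n",
              x$scheme, x$kernel, x$gamma, x$cost, x$pos_class_weight, x$threshold))
  invisible(x)
}

#' Read a model configuration from a YAML file
#'
#' Accepts both the short SVM-light style keys (`t` as 0 = linear,
#' 1 = poly, 2 = rbf; `g`, `c`, `j`) and long aliases (`kernel`, `gamma`,
#' `cost`, `pos_class_weight`), plus `threshold` and `scheme`.
#'
#' @param path Path to a YAML file.
#' @return A `model_config`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("cannot read config file: %s", path))
  y <- yaml::read_yaml(path)
  kernel <- y$kernel
  if (!is.null(y$t)) kernel <- c("linear", "poly", "rbf")[as.integer(y$t) + 1L]
  model_config(
    scheme = y$scheme %||% "DPC",
    kernel = kernel %||% "rbf",
    gamma = y$gamma %||% y$g %||% 0.001,
    cost = y$cost %||% y$c %||% 5,
    pos_class_weight = y$pos_class_weight %||% y$j %||% 1,
    threshold = y$threshold %||% -0.4)
}

#' Write a model configuration to YAML
#'
#' @param config A `model_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_config <- function(config, path) {
  stopifnot(inherits(config, "model_config"))
  yaml::write_yaml(list(
    scheme = config$scheme,
    t = match(config$kernel, c("linear", "poly", "rbf")) - 1L,
    g = config$gamma, c = config$cost, j = config$pos_class_weight,
    threshold = config$threshold), path)
  invisible(path)
}

# drop records too short for the scheme, with a logged warning
.drop_unencodable <- function(ds, scheme, role) {
  short <- nchar(ds$seq) < scheme_min_length(scheme)
  if (any(short)) {
    warn(sprintf("dropping %d %s record(s) too short for scheme %s: %s",
                 sum(short), role, scheme,
                 paste(head(ds$id[short], 5L), collapse = ", ")))
  }
  list(kept = ds[!short, , drop = FALSE], dropped = ds$id[short])
}

#' Train a toxicity classifier
#'
#' Encodes both classes under the configured scheme, labels toxic = +1 and
#' nontoxic = -1, and fits a soft-margin kernel SVM with the configured
#' kernel, gamma, cost and per-class cost ratio. The returned model's
#' [decision_score()] is the signed decision value, positive side = toxic.
#' Records too short for the scheme are dropped with a warning. Training is
#' deterministic given identical inputs and seed.
#'
#' @param pos,neg Dataset tibbles of toxic and non-toxic peptides.
#' @param config A [model_config()].
#' @param seed Integer seed recorded with the model.
#' @return An object of class `toxin_model`.
#' @export
train_model <- function(pos, neg, config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  .check_dataset(pos, "pos")
  .check_dataset(neg, "neg")
  dp <- .drop_unencodable(pos, config$scheme, "positive")
  dn <- .drop_unencodable(neg, config$scheme, "negative")
  if (nrow(dp$kept) < 2L || nrow(dn$kept) < 2L) {
    abort(sprintf(
      "each class needs >= 2 encodable peptides under scheme %s (dropped: %s)",
      config$scheme,
      paste(c(dp$dropped, dn$dropped), collapse = ", ")),
      class = "peptox_training_error")
  }
  x <- rbind(.encode_matrix(dp$kept$seq, config$scheme),
             .encode_matrix(dn$kept$seq, config$scheme))
  y <- factor(c(rep("toxic", nrow(dp$kept)), rep("nontoxic", nrow(dn$kept))),
              levels = c("toxic", "nontoxic"))
  set.seed(seed)
  fit <- e1071::svm(
    x, y, type = "C-classification", scale = FALSE,
    kernel = switch(config$kernel, rbf = "radial", poly = "polynomial",
                    linear = "linear"),
    gamma = config$gamma, cost = config$cost, degree = config$degree,
    class.weights = c(toxic = config$pos_class_weight, nontoxic = 1))
  # orient decision values so that positive = toxic
  dv <- attr(predict(fit, x[1:2, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  sign_mult <- if (startsWith(colnames(dv)[1], "toxic")) 1 else -1
  structure(list(fit = fit, config = config, sign = sign_mult,
                 meta = list(n_pos = nrow(dp$kept), n_neg = nrow(dn$kept),
                             seed = as.integer(seed),
                             dropped = c(dp$dropped, dn$dropped))),
            class = "toxin_model")
}

#' @export
print.toxin_model <- function(x, ...) {
  cat(sprintf("<toxin_model> scheme=%s kernel=%s (trained on %d pos / %d neg, seed %d)\n",
              x$config$scheme, x$config$kernel, x$meta$n_pos, x$meta$n_neg,
              x$meta$seed))
  cat(sprintf("decision threshold %g; scores >= threshold are called toxic\n",
              x$config$threshold))
  invisible(x)
}

#' Raw decision scores of peptides
#'
#' Larger scores are more toxic-like; the score is the signed SVM decision
#' value (no clipping, no calibration).
#'
#' @param model A [train_model()] fit.
#' @param seq Character vector of peptides, or a dataset tibble.
#' @return Numeric vector of scores.
#' @export
decision_score <- function(model, seq) {
  stopifnot(inherits(model, "toxin_model"))
  if (is.data.frame(seq)) seq <- seq$seq
  seq <- toupper(seq)
  short <- nchar(seq) < scheme_min_length(model$config$scheme)
  if (any(short)) {
    .stop_domain(sprintf("%d peptide(s) too short to encode under scheme %s",
                         sum(short), model$config$scheme))
  }
  x <- .encode_matrix(seq, model$config$scheme)
  dv <- attr(predict(model$fit, x, decision.values = TRUE), "decision.values")
  as.numeric(dv) * model$sign
}

#' Predict toxicity calls for peptides
#'
#' A peptide is called toxic when its decision score is greater than or equal
#' to the threshold.
#'
#' @param object A [train_model()] fit.
#' @param newdata Character vector of peptides or a dataset tibble.
#' @param threshold Decision threshold; defaults to the model's configured
#'   threshold.
#' @param ... Unused.
#' @return Tibble with `id`, `seq`, `score`, `call`.
#' @export
predict.toxin_model <- function(object, newdata,
                                threshold = object$config$threshold, ...) {
  if (is.data.frame(newdata)) {
    ids <- newdata$id
    seqs <- newdata$seq
  } else {
    ids <- paste0("seq", seq_along(newdata))
    seqs <- as.character(newdata)
  }
  score <- decision_score(object, seqs)
  tibble(id = ids, seq = toupper(seqs), score = score,
         call = ifelse(score >= threshold, "toxic", "nontoxic"))
}

#' Hybrid motif-boosted score
#'
#' When a query peptide carries any toxic-peptide motif, its SVM score is
#' increased by a fixed boost (default 5) before thresholding. With the
#' default boost, a motif hit forces a toxic call at any threshold in the
#' usual decision-value range, irrespective of the SVM prediction.
#'
#' @param base Numeric vector of raw decision scores.
#' @param motif_hit Logical vector: does the peptide carry a motif hit?
#' @param boost Score increment applied on a hit.
#' @return Numeric vector of hybrid scores.
#' @export
#' @examples
#' hybrid_score(-2, TRUE)   # 3: toxic at any paper-range threshold
#' hybrid_score(-2, FALSE)  # -2
hybrid_score <- function(base, motif_hit, boost = 5) {
  base + boost * as.numeric(motif_hit)
}

#' Save / load a trained model
#'
#' The archive stores the configuration block, the fitted SVM parameters and
#' training metadata; a reloaded model reproduces decision scores to within
#' 1e-9.
#'
#' @param model A `toxin_model`.
#' @param path File path for the model archive.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "toxin_model"))
  saveRDS(list(format = "peptox_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("cannot read model file: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e) NULL)
  if (is.null(obj) || !identical(obj$format, "peptox_model")) {
    .stop_format(sprintf("%s is not a peptox model archive", path))
  }
  obj$model
}
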