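# Application utilities: single-mutant enumeration and ranking, greedy
# iterative design, sliding-window protein scanning, and batch prediction.
# Coordinates are 1-based inclusive throughout.

#' Enumerate all single-residue mutants of a peptide
#'
#' @param seq A single peptide over the natural residues.
#' @return Tibble of exactly `19 * nchar(seq)` mutants ordered by position
#'   then alphabetical replacement: `position`, `from`, `to`, `mutant`. The
#'   parent sequence itself is excluded.
#' @export
#' @examples
#' nrow(enumerate_single_mutants("ACDE"))  # 76
enumerate_single_mutants <- function(seq) {
  seq <- .check_seq(seq, 1L)
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  out <- tidyr::expand_grid(position = seq_len(L), to = .AA)
  out$from <- ch[out$position]
  out <- out[out$to != out$from, , drop = FALSE]
  out$mutant <- vapply(seq_len(nrow(out)), function(i) {
    s <- ch
    s[out$position[i]] <- out$to[i]
    paste(s, collapse = "")
  }, character(1))
  out[, c("position", "from", "to", "mutant")]
}

#' Score and rank all single mutants of a peptide
#'
#' Scores every single mutant plus the parent with the model and sorts by
#' score in the requested direction (SVM score is proportional to toxicity).
#' Ties are broken by position then replacement residue; the parent sorts
#' first among ties and is reported with `delta = 0`.
#'
#' @param seq Parent peptide.
#' @param model A [train_model()] fit.
#' @param direction `"minimize"` (design less-toxic variants) or
#'   `"maximize"`.
#' @return Tibble: `mutant`, `position`, `from`, `to`, `score`, `delta`
#'   (score minus parent score), sorted per `direction`.
#' @export
rank_mutants <- function(seq, model, direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  stopifnot(inherits(model, "toxin_model"))
  seq <- .check_seq(seq, 1L)
  mut <- enumerate_single_mutants(seq)
  all_rows <- dplyr::bind_rows(
    tibble(position = 0L, from = "", to = "", mutant = seq),
    mut)
  all_rows$score <- decision_score(model, all_rows$mutant)
  parent_score <- all_rows$score[1]
  all_rows$delta <- all_rows$score - parent_score
  ord <- order(if (direction == "minimize") all_rows$score else -all_rows$score,
               all_rows$position, all_rows$to)
  out <- all_rows[ord, c("mutant", "position", "from", "to", "score", "delta")]
  attr(out, "parent") <- seq
  attr(out, "parent_score") <- parent_score
  attr(out, "direction") <- direction
  out
}

#' Greedy iterative single-mutation design
#'
#' Repeatedly applies the best single mutation (per [rank_mutants()]) until no
#' mutation improves the score in the requested direction or `max_rounds` is
#' reached.
#'
#' @inheritParams rank_mutants
#' @param max_rounds Hard cap on design rounds (termination guarantee).
#' @return Tibble with one row per accepted round (round 0 = parent):
#'   `round`, `seq`, `score`, `mutation` (e.g. `"C3A"`).
#' @export
design_peptide <- function(seq, model, direction = c("minimize", "maximize"),
                           max_rounds = 10L) {
  direction <- match.arg(direction)
  current <- .check_seq(seq, 1L)
  score <- decision_score(model, current)
  path <- tibble(round = 0L, seq = current, score = score, mutation = NA_character_)
  better <- if (direction == "minimize") function(a, b) a < b else function(a, b) a > b
  for (r in seq_len(max_rounds)) {
    ranked <- rank_mutants(current, model, direction)
    top <- ranked[ranked$position > 0L, ][1, ]
    if (!better(top$score, score)) break
    current <- top$mutant
    score <- top$score
    path <- dplyr::bind_rows(path, tibble(
      round = r, seq = current, score = score,
      mutation = sprintf("%s%d%s", top$from, top$position, top$to)))
  }
  path
}

#' Sliding-window toxicity scan of a protein
#'
#' Generates every overlapping window of the given width (step 1), scores each
#' with the supplied predictor (a trained SVM model or a quantitative matrix)
#' and calls it at the threshold. A per-position track (the maximum score over
#' all windows covering each position) is attached as attribute
#' `position_track`.
#'
#' @param protein A single protein sequence, natural residues, at least
#'   `window` long.
#' @param predictor A `toxin_model` or `quant_matrix`.
#' @param window Window width in residues (default 10).
#' @param threshold Call threshold; defaults to the model's configured
#'   threshold or the matrix-mode default.
#' @return Tibble of class `protein_scan`: `start`, `end` (1-based,
#'   inclusive), `seq`, `score`, `call`, ordered by `start`.
#' @export
scan_protein <- function(protein, predictor, window = 10L, threshold = NULL) {
  protein <- .check_seq(protein, 1L, "protein")
  L <- nchar(protein)
  if (L < window) {
    .stop_domain(sprintf(
      "protein of length %d is shorter than the window %d; use a smaller window",
      L, window))
  }
  starts <- seq_len(L - window + 1L)
  wins <- substring(protein, starts, starts + window - 1L)
  if (inherits(predictor, "toxin_model")) {
    score <- decision_score(predictor, wins)
    if (is.null(threshold)) threshold <- predictor$config$threshold
  } else if (inherits(predictor, "quant_matrix")) {
    score <- qm_score(wins, predictor)
    if (is.null(threshold)) threshold <- qm_default_threshold(predictor$mode)
  } else {
    .stop_domain("predictor must be a toxin_model or a quant_matrix")
  }
  out <- tibble(start = starts, end = starts + window - 1L, seq = wins,
                score = score,
                call = ifelse(score >= threshold, "toxic", "nontoxic"))
  track <- vapply(seq_len(L), function(p) {
    max(score[starts <= p & starts + window - 1L >= p])
  }, numeric(1))
  class(out) <- c("protein_scan", class(out))
  attr(out, "position_track") <- track
  attr(out, "window") <- as.integer(window)
  attr(out, "threshold") <- threshold
  out
}

#' Per-position maximum-score track of a protein scan
#'
#' @param scan A [scan_protein()] result.
#' @return Numeric vector, one value per protein position.
#' @export
position_track <- function(scan) {
  stopifnot(inherits(scan, "protein_scan"))
  attr(scan, "position_track")
}

#' Write a protein scan as BED
#'
#' Converts the 1-based inclusive window coordinates to BED's 0-based
#' half-open convention at the writer.
#'
#' @param scan A [scan_protein()] result.
#' @param path Output path.
#' @param name Feature name column (default the window sequence).
#' @return `path`, invisibly.
#' @export
write_scan_bed <- function(scan, path, name = scan$seq) {
  stopifnot(inherits(scan, "protein_scan"))
  df <- data.frame(chrom = "protein", chromStart = scan$start - 1L,
                   chromEnd = scan$end, name = name, score = scan$score,
                   strand = ".")
  write.table(df, path, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Predict toxicity for every record in a dataset
#'
#' One row per input record in input order. Records the model cannot encode
#' (too short for the scheme) are reported with a per-record error message
#' instead of aborting the batch.
#'
#' @param ds Dataset tibble.
#' @param model A [train_model()] fit.
#' @param threshold Decision threshold (default the model's configured one).
#' @return Tibble: `id`, `seq`, `score`, `call`, `error`.
#' @export
batch_predict <- function(ds, model, threshold = model$config$threshold) {
  .check_dataset(ds)
  stopifnot(inherits(model, "toxin_model"))
  ok <- nchar(ds$seq) >= scheme_min_length(model$config$scheme) &
    .is_natural(toupper(ds$seq))
  score <- rep(NA_real_, nrow(ds))
  if (any(ok)) score[ok] <- decision_score(model, ds$seq[ok])
  tibble(
    id = ds$id, seq = toupper(ds$seq), score = score,
    call = ifelse(ok, ifelse(score >= threshold, "toxic", "nontoxic"),
                  NA_character_),
    error = ifelse(ok, NA_character_,
                   sprintf("cannot encode under scheme %s", model$config$scheme)))
}
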