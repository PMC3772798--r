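# Position-specific quantitative matrices: per-position percent residue (or
# dipeptide) frequencies per class, their difference matrix, cumulative
# peptide scoring, per-position extremes, and substitution reports.
#
# Positions are 1-based from the N-terminus. A peptide shorter than max_len
# contributes only to the columns it reaches; each column's denominator is
# the number of peptides reaching that position, which keeps every reached
# column normalized to 100.

#' Per-position percent frequency table
#'
#' `cell(r, p)` is 100 times the fraction of peptides whose element at
#' position `p` is `r`, among peptides long enough to have a position `p`.
#' In `mono` mode elements are residues (20 rows, `max_len` columns); in
#' `dipep` mode the element at `p` is the overlapping dipeptide starting at
#' `p` (400 rows, `max_len - 1` columns).
#'
#' @param ds Dataset tibble; every record must be at most `max_len` residues.
#' @param mode `"mono"` or `"dipep"`.
#' @param max_len Matrix depth in residues (default 35).
#' @return Numeric matrix with a `position_counts` attribute giving each
#'   column's denominator.
#' @export
position_frequency <- function(ds, mode = c("mono", "dipep"), max_len = 35L) {
  mode <- match.arg(mode)
  .check_dataset(ds)
  if (!all(.is_natural(ds$seq))) {
    .stop_domain("dataset contains non-natural residues; run filter_dataset() first")
  }
  len <- nchar(ds$seq)
  if (any(len > max_len)) {
    .stop_domain(sprintf(
      "%d record(s) longer than max_len=%d; run filter_dataset() first",
      sum(len > max_len), max_len))
  }
  span <- if (mode == "mono") 0L else 1L
  P <- max_len - span
  rows <- if (mode == "mono") .AA else .DIPEP
  mat <- matrix(0, nrow = length(rows), ncol = P,
                dimnames = list(rows, paste0("P", seq_len(P))))
  counts <- integer(P)
  for (p in seq_len(P)) {
    has <- len >= p + span
    counts[p] <- sum(has)
    if (counts[p] > 0L) {
      el <- substr(ds$seq[has], p, p + span)
      mat[, p] <- 100 * tabulate(match(el, rows), length(rows)) / counts[p]
    }
  }
  attr(mat, "position_counts") <- counts
  mat
}

#' Build a quantitative matrix (positive minus negative class)
#'
#' The per-position percent-frequency table of the negative class is
#' subtracted from that of the positive class, giving a residue-by-position
#' (20 x `max_len`) or dipeptide-by-position (400 x `max_len - 1`) table of
#' differences in `[-100, 100]`. Per-position denominators of both classes
#' are retained for reporting.
#'
#' @param pos,neg Length-filtered dataset tibbles.
#' @inheritParams position_frequency
#' @return An object of class `quant_matrix`.
#' @export
build_qm <- function(pos, neg, mode = c("mono", "dipep"), max_len = 35L) {
  mode <- match.arg(mode)
  fp <- position_frequency(pos, mode, max_len)
  fn <- position_frequency(neg, mode, max_len)
  cells <- fp - fn
  attr(cells, "position_counts") <- NULL
  structure(
    list(mode = mode, max_len = as.integer(max_len), cells = cells,
         position_counts_pos = attr(fp, "position_counts"),
         position_counts_neg = attr(fn, "position_counts"),
         n_pos = nrow(pos), n_neg = nrow(neg)),
    class = "quant_matrix")
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("<quant_matrix> mode=%s  %d x %d  (built from %d pos / %d neg peptides)\n",
              x$mode, nrow(x$cells), ncol(x$cells), x$n_pos, x$n_neg))
  cat(sprintf("cell range [%.2f, %.2f]; positions 1-based from N-terminus\n",
              min(x$cells), max(x$cells)))
  invisible(x)
}

# row index of each positional element of a peptide under a qm
.qm_elements <- function(seq, qm) {
  n <- nchar(seq)
  if (qm$mode == "mono") {
    match(strsplit(seq, "", fixed = TRUE)[[1]], rownames(qm$cells))
  } else {
    match(substring(seq, 1:(n - 1L), 2:n), rownames(qm$cells))
  }
}

#' Cumulative quantitative-matrix score of peptides
#'
#' Sums, over the positions a peptide reaches, the matrix cell of the element
#' observed at each position. Larger scores are more toxic-like.
#'
#' @param seq Character vector of peptides, each at most `qm$max_len`
#'   residues (and at least 2 in `dipep` mode).
#' @param qm A [build_qm()] matrix.
#' @return Numeric vector of scores.
#' @export
qm_score <- function(seq, qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  vapply(seq, function(s) {
    s <- .check_seq(s, if (qm$mode == "dipep") 2L else 1L)
    if (nchar(s) > qm$max_len) {
      .stop_domain(sprintf("peptide of length %d exceeds the matrix depth max_len=%d",
                           nchar(s), qm$max_len))
    }
    ridx <- .qm_elements(s, qm)
    sum(qm$cells[cbind(ridx, seq_along(ridx))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default decision threshold of a quantitative matrix
#'
#' @param mode `"mono"` (threshold 20) or `"dipep"` (threshold 5).
#' @return Numeric threshold.
#' @export
qm_default_threshold <- function(mode = c("mono", "dipep")) {
  switch(match.arg(mode), mono = 20, dipep = 5)
}

#' Classify quantitative-matrix scores
#'
#' A peptide is called toxic when its cumulative score is greater than or
#' equal to the threshold (scores exactly at the threshold are toxic).
#'
#' @param score Numeric vector of [qm_score()] values.
#' @param qm Optional matrix whose mode picks the default threshold.
#' @param threshold Decision threshold; defaults to 20 for `mono` and 5 for
#'   `dipep` matrices.
#' @return Character vector of `"toxic"` / `"nontoxic"`.
#' @export
qm_classify <- function(score, qm = NULL, threshold = NULL) {
  if (is.null(threshold)) {
    threshold <- qm_default_threshold(if (is.null(qm)) "mono" else qm$mode)
  }
  ifelse(score >= threshold, "toxic", "nontoxic")
}

#' Maximum and minimum scoring elements at every position
#'
#' @param qm A [build_qm()] matrix.
#' @return Tibble with `position`, `max_element`, `max_score`, `min_element`,
#'   `min_score`; ties are broken alphabetically.
#' @export
position_extremes <- function(qm) {
  stopifnot(inherits(qm, "quant_matrix"))
  imax <- apply(qm$cells, 2L, which.max)
  imin <- apply(qm$cells, 2L, which.min)
  tibble(position = seq_len(ncol(qm$cells)),
         max_element = rownames(qm$cells)[imax],
         max_score = qm$cells[cbind(imax, seq_along(imax))],
         min_element = rownames(qm$cells)[imin],
         min_score = qm$cells[cbind(imin, seq_along(imin))])
}

#' Per-position substitution report for a peptide
#'
#' For each position of the query peptide, reports the current element's cell
#' score and the single-element substitution that maximizes (or minimizes) the
#' cell value at that position, with the score delta. Because positions are
#' scored independently in `mono` mode, applying every suggested maximizing
#' substitution attains the [position_extremes()] maximum path.
#'
#' @param seq A single peptide (at most `qm$max_len` residues).
#' @param qm A [build_qm()] matrix.
#' @param direction Optimize toward maximum or minimum toxicity score.
#' @return Tibble with `position`, `element`, `score`, `suggestion`,
#'   `suggestion_score`, `delta` (`suggestion_score - score`); the peptide's
#'   total score and the direction are attached as attributes `total_score`
#'   and `direction`.
#' @export
qms_report <- function(seq, qm, direction = c("maximize", "minimize")) {
  direction <- match.arg(direction)
  stopifnot(inherits(qm, "quant_matrix"))
  seq <- .check_seq(seq, if (qm$mode == "dipep") 2L else 1L)
  if (nchar(seq) > qm$max_len) {
    .stop_domain(sprintf("peptide of length %d exceeds the matrix depth max_len=%d",
                         nchar(seq), qm$max_len))
  }
  ridx <- .qm_elements(seq, qm)
  pos <- seq_along(ridx)
  pick <- if (direction == "maximize") which.max else which.min
  best <- vapply(pos, function(p) pick(qm$cells[, p]), integer(1))
  out <- tibble(
    position = pos,
    element = rownames(qm$cells)[ridx],
    score = qm$cells[cbind(ridx, pos)],
    suggestion = rownames(qm$cells)[best],
    suggestion_score = qm$cells[cbind(best, pos)])
  out$delta <- out$suggestion_score - out$score
  attr(out, "total_score") <- sum(out$score)
  attr(out, "direction") <- direction
  out
}

#' Serialize a quantitative matrix to TSV
#'
#' Writes `#`-prefixed comment lines (mode, depth, class sizes, per-position
#' denominators and the indexing convention), then a header row and one row
#' per element.
#'
#' @param qm A [build_qm()] matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qm <- function(qm, path) {
  stopifnot(inherits(qm, "quant_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# quant_matrix",
    sprintf("# mode=%s", qm$mode),
    sprintf("# max_len=%d", qm$max_len),
    sprintf("# n_pos=%d n_neg=%d", qm$n_pos, qm$n_neg),
    sprintf("# position_counts_pos=%s", paste(qm$position_counts_pos, collapse = ",")),
    sprintf("# position_counts_neg=%s", paste(qm$position_counts_neg, collapse = ",")),
    "# positions 1-based from N-terminus; column denominator = peptides reaching the position"
  ), con)
  df <- data.frame(element = rownames(qm$cells), qm$cells,
                   check.names = FALSE, row.names = NULL)
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a quantitative matrix written by [write_qm()]
#'
#' @param path Path to a TSV written by [write_qm()].
#' @return A `quant_matrix` object.
#' @export
read_qm <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("cannot read matrix file: %s", path))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) sub(sprintf("^# %s=", key), "",
                           grep(sprintf("^# %s=", key), hdr, value = TRUE)[1])
  mode <- get("mode")
  if (!mode %in% c("mono", "dipep")) .stop_format(sprintf("%s: missing mode header", path))
  max_len <- as.integer(get("max_len"))
  nn <- strsplit(sub("^# ", "", grep("^# n_pos=", hdr, value = TRUE)[1]), " ")[[1]]
  body <- read.delim(text = lines[!grepl("^#", lines)], check.names = FALSE)
  cells <- as.matrix(body[, -1, drop = FALSE])
  rownames(cells) <- body[[1]]
  structure(
    list(mode = mode, max_len = max_len, cells = cells,
         position_counts_pos = as.integer(strsplit(get("position_counts_pos"), ",")[[1]]),
         position_counts_neg = as.integer(strsplit(get("position_counts_neg"), ",")[[1]]),
         n_pos = as.integer(sub("n_pos=", "", nn[1])),
         n_neg = as.integer(sub("n_neg=", "", nn[2]))),
    class = "quant_matrix")
}
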