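# Sequence-to-vector encoders: whole and terminal amino acid composition,
# dipeptide composition, terminal one-hot (binary) profiles, and the
# between-class composition comparison. Feature order is alphabetical
# one-letter code everywhere.

#' Amino acid composition (AAC)
#'
#' Percent composition of each of the 20 residues:
#' `Comp(i) = 100 * R_i / N`, where `R_i` is the count of residue `i` and `N`
#' the peptide length. Features are ordered alphabetically (A, C, D, ..., Y)
#' and sum to 100.
#'
#' @param seq A single peptide string over the 20 natural residues.
#' @return Named numeric vector of length 20 (percentages).
#' @export
#' @examples
#' aac("ACDE")
aac <- function(seq) {
  seq <- .check_seq(seq, 1L)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  setNames(100 * tabulate(match(ch, .AA), 20L) / length(ch), .AA)
}

#' Dipeptide composition (DPC)
#'
#' Percent fraction of each of the 400 ordered residue pairs over the `N - 1`
#' overlapping windows of the peptide. Feature order is alphabetical by first
#' then second residue (AA, AC, ..., YY); values sum to 100.
#'
#' @inheritParams aac
#' @return Named numeric vector of length 400 (percentages).
#' @export
#' @examples
#' head(sort(dpc("ACAC"), decreasing = TRUE))
dpc <- function(seq) {
  seq <- .check_seq(seq, 1L)
  n <- nchar(seq)
  if (n < 2L) {
    .stop_domain("dipeptide composition undefined for a single-residue peptide")
  }
  pairs <- substring(seq, 1:(n - 1L), 2:n)
  setNames(100 * tabulate(match(pairs, .DIPEP), 400L) / (n - 1L), .DIPEP)
}

#' Terminal amino acid composition (NkAAC / CkAAC)
#'
#' Amino acid composition of the first `k` N-terminal (`end = "N"`) or last
#' `k` C-terminal (`end = "C"`) residues.
#'
#' @inheritParams aac
#' @param end Which terminus the window is anchored to.
#' @param k Window length in residues; the peptide must be at least `k` long
#'   (no padding).
#' @return Named numeric vector of length 20 (percentages).
#' @export
terminal_composition <- function(seq, end = c("N", "C"), k = 5L) {
  end <- match.arg(end)
  seq <- .check_seq(seq, 1L)
  n <- nchar(seq)
  if (n < k) {
    .stop_domain(sprintf(
      "peptide of length %d is %d residue(s) short of the %s-terminal window k=%d",
      n, k - n, end, k))
  }
  win <- if (end == "N") substr(seq, 1L, k) else substr(seq, n - k + 1L, n)
  aac(win)
}

#' Terminal one-hot binary profile (NTk / CTk)
#'
#' One-hot encodes each position of a fixed terminal window, capturing residue
#' order as well as composition. Each position contributes a 20-entry block
#' (alphabetical residue order) that sums to exactly 1; blocks are
#' concatenated N-to-C, giving `k * 20` entries.
#'
#' @inheritParams terminal_composition
#' @return Named numeric vector of length `k * 20` with entries in `{0, 1}`.
#' @export
binary_profile <- function(seq, end = c("N", "C"), k = 10L) {
  end <- match.arg(end)
  seq <- .check_seq(seq, 1L)
  n <- nchar(seq)
  if (n < k) {
    .stop_domain(sprintf(
      "peptide of length %d is too short for a %s-terminal binary profile of width %d",
      n, end, k))
  }
  win <- if (end == "N") substr(seq, 1L, k) else substr(seq, n - k + 1L, n)
  ch <- strsplit(win, "", fixed = TRUE)[[1]]
  m <- matrix(0, nrow = k, ncol = 20L)
  m[cbind(seq_len(k), match(ch, .AA))] <- 1
  setNames(as.vector(t(m)),
           paste0(rep(sprintf("p%02d", seq_len(k)), each = 20L), "_", .AA))
}

# ---- scheme machinery ----

# parse a scheme name into its components
.parse_scheme <- function(scheme) {
  s <- toupper(scheme)
  if (s == "AAC") return(list(type = "aac", size = 20L, min_len = 1L))
  if (s == "DPC") return(list(type = "dpc", size = 400L, min_len = 2L))
  m <- regmatches(s, regexec("^([NC])([0-9]+)AAC$", s))[[1]]
  if (length(m)) {
    k <- as.integer(m[3])
    return(list(type = "terminal", end = m[2], k = k, size = 20L, min_len = k))
  }
  m <- regmatches(s, regexec("^([NC])T([0-9]+)$", s))[[1]]
  if (length(m)) {
    k <- as.integer(m[3])
    return(list(type = "binary", end = m[2], k = k, size = 20L * k, min_len = k))
  }
  .stop_domain(sprintf(
    "unknown feature scheme '%s' (use AAC, DPC, N<k>AAC, C<k>AAC, NT<k> or CT<k>)",
    scheme))
}

#' Minimum peptide length a scheme can encode
#'
#' @param scheme Scheme name: `"AAC"`, `"DPC"`, `"N5AAC"`, `"C10AAC"`,
#'   `"NT10"`, `"CT5"`, ...
#' @return Integer minimum length.
#' @export
scheme_min_length <- function(scheme) .parse_scheme(scheme)$min_len

# encode a character vector of peptides into an n x d feature matrix
.encode_matrix <- function(seqs, scheme) {
  sc <- .parse_scheme(scheme)
  f <- switch(sc$type,
    aac      = function(s) aac(s),
    dpc      = function(s) dpc(s),
    terminal = function(s) terminal_composition(s, sc$end, sc$k),
    binary   = function(s) binary_profile(s, sc$end, sc$k))
  m <- t(vapply(seqs, f, numeric(sc$size), USE.NAMES = FALSE))
  colnames(m) <- names(f(seqs[[1]]))
  rownames(m) <- NULL
  m
}

#' Encode a whole dataset under a named feature scheme
#'
#' @param ds Dataset tibble.
#' @inheritParams scheme_min_length
#' @return Tibble with `id` followed by one column per feature; the scheme is
#'   recorded in the `scheme` attribute.
#' @export
encode_dataset <- function(ds, scheme = "DPC") {
  .check_dataset(ds)
  short <- nchar(ds$seq) < scheme_min_length(scheme)
  if (any(short)) {
    .stop_domain(sprintf(
      "%d record(s) too short for scheme %s (e.g. %s); filter them out first",
      sum(short), scheme, paste(head(ds$id[short], 3L), collapse = ", ")))
  }
  m <- .encode_matrix(ds$seq, scheme)
  out <- dplyr::bind_cols(tibble(id = ds$id), as_tibble(m))
  attr(out, "scheme") <- toupper(scheme)
  out
}

#' Write an encoded feature table to CSV
#'
#' The scheme is recorded in a leading `#` comment line, followed by a header
#' row of feature names and one row per peptide.
#'
#' @inheritParams encode_dataset
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ds, scheme = "DPC", path) {
  ft <- encode_dataset(ds, scheme)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scheme=%s feature_order=alphabetical", toupper(scheme)), con)
  write.table(ft, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare per-residue composition between two classes
#'
#' Computes each peptide's amino acid composition, averages it within class,
#' and tests each residue for a between-class location difference with a
#' two-sided Welch (unequal-variance) t test. Dominance is called from
#' Holm-adjusted p values so the family of 20 simultaneous residue tests is
#' controlled at `alpha`: `"positive"` (enriched in `pos`), `"negative"`
#' (enriched in `neg`), or `"none"`.
#'
#' @param pos,neg Dataset tibbles for the positive (toxic) and negative
#'   (non-toxic) classes.
#' @param alpha Familywise significance level for dominance calls.
#' @return Tibble with one row per residue: `residue`, `mean_pos`, `mean_neg`,
#'   `difference` (`mean_pos - mean_neg`), `p_value` (raw Welch),
#'   `p_adjusted` (Holm), `dominance`. A class with fewer than 2 peptides
#'   yields missing p values (means are still reported).
#' @export
composition_comparison <- function(pos, neg, alpha = 0.05) {
  .check_dataset(pos, "pos")
  .check_dataset(neg, "neg")
  mp <- .encode_matrix(pos$seq, "AAC")
  mn <- .encode_matrix(neg$seq, "AAC")
  mean_pos <- colMeans(mp)
  mean_neg <- colMeans(mn)
  p <- rep(NA_real_, 20L)
  if (nrow(mp) >= 2L && nrow(mn) >= 2L) {
    p <- vapply(seq_len(20L), function(i) {
      tryCatch(t.test(mp[, i], mn[, i])$p.value, error = function(e) NA_real_)
    }, numeric(1))
  }
  p_adj <- p.adjust(p, method = "holm")
  diff <- mean_pos - mean_neg
  dominance <- ifelse(!is.na(p_adj) & p_adj < alpha & diff != 0,
                      ifelse(diff > 0, "positive", "negative"), "none")
  out <- tibble(residue = .AA, mean_pos = unname(mean_pos),
                mean_neg = unname(mean_neg), difference = unname(diff),
                p_value = p, p_adjusted = p_adj, dominance = dominance)
  class(out) <- c("composition_comparison", class(out))
  out
}
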