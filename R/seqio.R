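# Peptide/protein record model, FASTA and plain-list I/O, and the
# dataset-preparation filters (length cap, natural residues, exact dedup).

#' Build a peptide dataset tibble
#'
#' The atom of all analyses is a record with an identifier, an upper-case
#' residue string, and a class label. Datasets are plain tibbles so they chain
#' directly into dplyr pipelines.
#'
#' @param seq Character vector of residue strings (lower case is folded up).
#' @param id Optional character vector of identifiers; defaults to
#'   `seq1...seqN`.
#' @param label Class label(s): `"toxic"`, `"nontoxic"` or `"unknown"`;
#'   recycled to the number of records.
#' @return A tibble with columns `id`, `seq`, `label`.
#' @export
#' @examples
#' peptide_dataset(c("ACDE", "GGKL"), label = "toxic")
peptide_dataset <- function(seq, id = NULL, label = "unknown") {
  if (length(seq) == 0L) .stop_domain("no sequences supplied")
  seq <- toupper(as.character(seq))
  if (is.null(id)) id <- paste0("seq", seq_along(seq))
  if (length(id) != length(seq)) .stop_domain("`id` and `seq` lengths differ")
  if (!all(label %in% c("toxic", "nontoxic", "unknown"))) {
    .stop_domain("labels must be 'toxic', 'nontoxic' or 'unknown'")
  }
  tibble(id = as.character(id), seq = seq,
         label = rep_len(as.character(label), length(seq)))
}

# make FASTA ids unique by appending a running suffix, with a warning
.disambiguate_ids <- function(id) {
  if (!anyDuplicated(id)) return(id)
  dup <- unique(id[duplicated(id)])
  new <- stats::ave(id, id, FUN = function(x) {
    if (length(x) == 1L) x else paste0(x, "_", seq_along(x))
  })
  warn(sprintf("duplicate FASTA ids disambiguated with running suffixes: %s",
               paste(head(dup, 5L), collapse = ", ")))
  new
}

#' Read peptides or proteins from a FASTA file
#'
#' Headers start with `>`; the first whitespace-delimited token is the record
#' id; blank lines are ignored and lower-case residues are folded to upper
#' case. No length or alphabet filtering is applied here (full-length proteins
#' are legitimate input for scanning); use [filter_dataset()] to apply the
#' dataset-preparation rules.
#'
#' @param path Path to a FASTA file.
#' @param label Class label applied to all records.
#' @return A dataset tibble (`id`, `seq`, `label`) in file order.
#' @export
read_fasta <- function(path, label = c("unknown", "toxic", "nontoxic")) {
  label <- match.arg(label)
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    .stop_io(sprintf("cannot read FASTA file: %s", path))
  }
  first <- grep("\\S", readLines(path, warn = FALSE), value = TRUE)
  if (length(first) == 0L) .stop_format(sprintf("%s is empty", path))
  if (!startsWith(trimws(first[[1]]), ">")) {
    .stop_format(sprintf("%s is not FASTA: first record must start with '>'", path))
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) .stop_format(sprintf("no FASTA records in %s", path))
  empty <- Biostrings::width(set) == 0L
  if (any(empty)) {
    .stop_format(sprintf("FASTA header '%s' has an empty sequence",
                         names(set)[which(empty)[1]]))
  }
  id <- sub("\\s.*$", "", names(set))
  id <- .disambiguate_ids(id)
  peptide_dataset(seq = toupper(as.character(set)), id = id, label = label)
}

#' Read a plain one-sequence-per-line peptide list
#'
#' Ids are auto-generated as `seq1...seqN`; blank lines are skipped.
#'
#' @inheritParams read_fasta
#' @return A dataset tibble.
#' @export
read_peptide_list <- function(path, label = c("unknown", "toxic", "nontoxic")) {
  label <- match.arg(label)
  if (!file.exists(path)) .stop_io(sprintf("cannot read peptide list: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) .stop_format(sprintf("%s contains no sequences", path))
  peptide_dataset(seq = lines, label = label)
}

#' Write a dataset to FASTA
#'
#' Sequences are wrapped at 60 columns. Reading the file back reproduces the
#' `(id, seq)` pairs in order.
#'
#' @param ds Dataset tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ds, path) {
  .check_dataset(ds)
  set <- Biostrings::AAStringSet(setNames(ds$seq, ds$id))
  ok <- tryCatch({
    Biostrings::writeXStringSet(set, filepath = path, width = 60L)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .stop_io(sprintf("cannot write FASTA file: %s", path))
  invisible(path)
}

#' Apply the dataset-preparation filters
#'
#' Retains records that are 1 to `max_len` residues long and contain only the
#' 20 natural amino acids, then removes exact duplicates of the same
#' `(seq, label)` pair keeping the first occurrence. Every dropped record is
#' logged with its reason; retrieve the log with [rejection_log()].
#'
#' Ambiguity codes (B, J, O, U, X, Z) and `*` count as non-natural and are
#' rejected, never translated. The filter is idempotent.
#'
#' @param ds Dataset tibble.
#' @param max_len Maximum retained length (default 35 residues).
#' @return The filtered tibble, with a `rejections` attribute holding a tibble
#'   of `id`, `seq`, `reason` for every dropped record.
#' @export
filter_dataset <- function(ds, max_len = 35L) {
  .check_dataset(ds, require_rows = FALSE)
  if (!"label" %in% names(ds)) ds$label <- "unknown"
  reason <- rep(NA_character_, nrow(ds))

  bad <- regexpr("[^ACDEFGHIKLMNPQRSTVWY]", ds$seq)
  nonnat <- bad > 0L
  reason[nonnat] <- sprintf("non-natural residue %s",
                            substr(ds$seq[nonnat], bad[nonnat], bad[nonnat]))
  len <- nchar(ds$seq)
  reason[is.na(reason) & len == 0L] <- "empty sequence"
  reason[is.na(reason) & len > max_len] <- sprintf("length>%d", max_len)

  key <- paste(ds$seq, ds$label, sep = "\r")
  ok <- is.na(reason)
  dup <- ok & duplicated(ifelse(ok, key, NA_character_), incomparables = NA)
  if (any(dup)) {
    first_id <- ds$id[match(key[dup], key)]
    reason[dup] <- sprintf("duplicate of %s", first_id)
  }

  kept <- ds[is.na(reason), , drop = FALSE]
  rej <- tibble(id = ds$id[!is.na(reason)], seq = ds$seq[!is.na(reason)],
                reason = reason[!is.na(reason)])
  out <- as_tibble(kept)
  attr(out, "rejections") <- rej
  out
}

#' Rejection log of the last [filter_dataset()] call
#'
#' @param ds A tibble returned by [filter_dataset()].
#' @return Tibble of `id`, `seq`, `reason` (empty if nothing was rejected).
#' @export
rejection_log <- function(ds) {
  attr(ds, "rejections") %||%
    tibble(id = character(), seq = character(), reason = character())
}
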