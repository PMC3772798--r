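# Desk-scale motif machinery: enumerative discovery of enriched ungapped
# k-mers in toxic peptides with PWM expansion, PWM scanning with an exact
# dynamic-programming null p-value and a Bonferroni-style E-value, motif-only
# prediction with abstention, MEME-format persistence, and an optional
# adapter to external MEME/MAST binaries.

.MOTIF_BACKGROUND <- 0.05   # uniform residue background
.MOTIF_SCALE <- 1000L       # log-odds integerization granularity for the null DP

#' Discover enriched motifs in toxic peptides
#'
#' Enumerates every ungapped k-mer (k in `widths`) occurring in the positive
#' peptides and scores each by its peptide-level enrichment odds ratio against
#' the negative peptides, with a +0.5 continuity correction:
#' `OR = ((a+0.5)/(n_pos-a+0.5)) / ((b+0.5)/(n_neg-b+0.5))` where `a`, `b`
#' count peptides containing the k-mer. Seeds are selected greedily by
#' decreasing odds (only OR > 1 qualifies), skipping any candidate that
#' overlaps an already-selected seed on all but at most one aligned position
#' (i.e. shares a common substring of length >= min(width) - 1). Each selected
#' seed is expanded into a position probability matrix from its exact matches
#' in the positives with +1 pseudocount per cell.
#'
#' @param pos,neg Dataset tibbles (positives must contain at least 10
#'   peptides long enough for the widest motif).
#' @param n_motifs Maximum number of motifs returned.
#' @param widths Integer vector of candidate motif widths.
#' @param seed Integer seed recorded with the motif set (discovery itself is
#'   deterministic).
#' @return A `motif_set`: list of motifs ordered by decreasing enrichment,
#'   each with `id`, `consensus`, `width`, `pwm` (width x 20, rows sum to 1),
#'   `enrichment`, `n_pos`, `n_neg`.
#' @export
discover_motifs <- function(pos, neg, n_motifs = 20L, widths = 4:8, seed = 1L) {
  .check_dataset(pos, "pos")
  .check_dataset(neg, "neg")
  widths <- sort(unique(as.integer(widths)))
  if (any(widths < 1L)) .stop_domain("motif widths must be positive")
  eligible <- sum(nchar(pos$seq) >= max(widths))
  if (eligible < 10L) {
    abort(sprintf(
      "motif discovery needs >= 10 positive peptides of length >= %d (have %d)",
      max(widths), eligible), class = "peptox_discovery_error")
  }

  n_pos <- nrow(pos)
  n_neg <- nrow(neg)
  cand <- purrr::map(widths, function(k) {
    a <- .kmer_peptide_counts(pos$seq, k)
    if (length(a) == 0L) return(NULL)
    b <- .kmer_peptide_counts(neg$seq, k)[names(a)]
    b[is.na(b)] <- 0L
    tibble(kmer = names(a), width = k, a = as.integer(a), b = as.integer(b),
           enrichment = ((a + 0.5) / (n_pos - a + 0.5)) /
                        ((b + 0.5) / (n_neg - b + 0.5)))
  })
  cand <- dplyr::bind_rows(cand)
  cand <- cand[cand$enrichment > 1, , drop = FALSE]
  cand <- cand[order(-cand$enrichment, -cand$a, cand$kmer), , drop = FALSE]

  selected <- character(0)
  for (i in seq_len(nrow(cand))) {
    if (length(selected) >= n_motifs) break
    k <- cand$kmer[i]
    if (!any(vapply(selected, .kmers_overlap, logical(1), k))) {
      selected <- c(selected, k)
    }
  }
  keep <- cand[match(selected, cand$kmer), , drop = FALSE]
  motifs <- purrr::pmap(keep, function(kmer, width, a, b, enrichment) {
    .expand_seed(kmer, pos$seq, enrichment, a, b)
  })
  motifs <- purrr::imap(motifs, function(m, i) {
    m$id <- sprintf("motif_%02d", i)
    m
  })
  structure(motifs, class = "motif_set",
            background = .MOTIF_BACKGROUND, seed = as.integer(seed))
}

# number of peptides containing each k-mer at least once
.kmer_peptide_counts <- function(seqs, k) {
  per <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  })
  table(unlist(per))
}

# do two seeds overlap on >= min(width) - 1 aligned positions?
.kmers_overlap <- function(a, b) {
  m <- min(nchar(a), nchar(b)) - 1L
  if (m < 1L) return(TRUE)
  subs <- function(s, w) unique(substring(s, 1:(nchar(s) - w + 1L), w:nchar(s)))
  any(subs(a, m) %in% subs(b, m))
}

# expand an exact seed into a +1-pseudocount PWM from its matches in pos
.expand_seed <- function(kmer, pos_seqs, enrichment, a, b) {
  w <- nchar(kmer)
  n_occ <- sum(vapply(pos_seqs, function(s) {
    lengths(regmatches(s, gregexpr(kmer, s, fixed = TRUE)))
  }, integer(1)))
  counts <- matrix(1, nrow = w, ncol = 20L, dimnames = list(NULL, .AA))
  idx <- match(strsplit(kmer, "", fixed = TRUE)[[1]], .AA)
  counts[cbind(seq_len(w), idx)] <- counts[cbind(seq_len(w), idx)] + n_occ
  structure(list(id = NA_character_, consensus = kmer, width = w,
                 pwm = counts / rowSums(counts), enrichment = enrichment,
                 n_sites = n_occ, n_pos = a, n_neg = b),
            class = "pep_motif")
}

#' @export
print.motif_set <- function(x, ...) {
  cat(sprintf("<motif_set> %d motif(s), uniform background %.2f\n",
              length(x), attr(x, "background")))
  for (m in x) {
    cat(sprintf("  %s  %-10s width %d  enrichment %.2f  (%d pos / %d neg peptides)\n",
                m$id, m$consensus, m$width, m$enrichment, m$n_pos, m$n_neg))
  }
  invisible(x)
}

#' @export
`[.motif_set` <- function(x, i) {
  structure(unclass(x)[i], class = "motif_set",
            background = attr(x, "background"), seed = attr(x, "seed"))
}

# integerized log-odds table and exact null tail probabilities for one motif.
# The null is i.i.d. uniform background per position; the score distribution
# is computed exactly (at .MOTIF_SCALE granularity) by convolving positions.
.motif_tables <- function(motif, bg = .MOTIF_BACKGROUND, scale = .MOTIF_SCALE) {
  S <- round(log2(motif$pwm / bg) * scale)
  storage.mode(S) <- "integer"
  dimnames(S) <- NULL
  dist <- 1
  lo <- 0L
  for (p in seq_len(motif$width)) {
    row <- S[p, ]
    rmin <- min(row)
    rmax <- max(row)
    nd <- numeric(length(dist) + (rmax - rmin))
    for (r in seq_len(20L)) {
      off <- row[r] - rmin
      idx <- seq_along(dist) + off
      nd[idx] <- nd[idx] + dist / 20
    }
    dist <- nd
    lo <- lo + rmin
  }
  # tail[i] = P(score_int >= lo + i - 1)
  tail_p <- rev(cumsum(rev(dist)))
  list(S = S, lo = lo, tail_p = tail_p)
}

# exact null p-value of integer scores under a prepared table
.motif_pvalue <- function(score_int, tab) {
  i <- score_int - tab$lo + 1L
  p <- numeric(length(i))
  p[i < 1L] <- 1
  inside <- i >= 1L & i <= length(tab$tail_p)
  p[inside] <- tab$tail_p[i[inside]]
  # scores above the support max cannot occur when computed from the same table
  p[i > length(tab$tail_p)] <- tab$tail_p[length(tab$tail_p)]
  p
}

# scan many sequences against a motif set; returns one hit tibble per seq
.scan_many <- function(seqs, motifs, evalue_max = 10) {
  stopifnot(inherits(motifs, "motif_set"))
  if (length(motifs) == 0L) .stop_domain("empty motif set")
  tabs <- lapply(motifs, .motif_tables)
  widths <- vapply(motifs, function(m) m$width, integer(1))
  lapply(seqs, function(s) {
    s <- .check_seq(s, 1L)
    L <- nchar(s)
    n_windows <- sum(pmax(0L, L - widths + 1L))
    hits <- vector("list", length(motifs))
    if (n_windows > 0L) {
      ridx <- match(strsplit(s, "", fixed = TRUE)[[1]], .AA)
      for (mi in seq_along(motifs)) {
        w <- widths[mi]
        if (L < w) next
        starts <- seq_len(L - w + 1L)
        S <- tabs[[mi]]$S
        sc <- integer(length(starts))
        for (p in seq_len(w)) sc <- sc + S[p, ridx[starts + p - 1L]]
        pv <- .motif_pvalue(sc, tabs[[mi]])
        ev <- pv * n_windows
        keep <- ev <= evalue_max
        if (any(keep)) {
          hits[[mi]] <- tibble(
            motif = motifs[[mi]]$id, consensus = motifs[[mi]]$consensus,
            start = starts[keep], width = w,
            match = substring(s, starts[keep], starts[keep] + w - 1L),
            score = sc[keep] / .MOTIF_SCALE, p_value = pv[keep],
            evalue = ev[keep])
        }
      }
    }
    out <- dplyr::bind_rows(hits)
    if (nrow(out) == 0L) {
      out <- tibble(motif = character(), consensus = character(),
                    start = integer(), width = integer(), match = character(),
                    score = numeric(), p_value = numeric(), evalue = numeric())
    }
    out[order(out$evalue, out$start), , drop = FALSE]
  })
}

#' Scan a sequence for motif hits
#'
#' Slides each motif's position probability matrix over the sequence. The
#' match score of a window is `sum(log2(pwm[p, res] / 0.05))`; its p-value is
#' the exact probability of an equal-or-better score under the i.i.d. uniform
#' background, computed by dynamic programming; the E-value is the p-value
#' times the total number of windows scanned across all motifs
#' (Bonferroni-style). Hits with `evalue <= evalue_max` are returned sorted by
#' increasing E-value. A sequence shorter than every motif yields an empty hit
#' list. Hit lists are nested: tightening `evalue_max` can only remove hits.
#'
#' @param seq A single sequence over the natural residues.
#' @param motifs A `motif_set` from [discover_motifs()] or
#'   [read_meme_motifs()].
#' @param evalue_max E-value cutoff (default 10).
#' @return Tibble of hits: `motif`, `consensus`, `start` (1-based), `width`,
#'   `match`, `score`, `p_value`, `evalue`.
#' @export
scan_motifs <- function(seq, motifs, evalue_max = 10) {
  .scan_many(seq, motifs, evalue_max)[[1]]
}

#' Motif-only prediction with abstention
#'
#' Calls a record toxic when at least one motif hit passes the E-value cutoff
#' and abstains otherwise. Paired with [pcp_coverage()], tightening the cutoff
#' trades coverage for precision.
#'
#' @param ds Dataset tibble.
#' @inheritParams scan_motifs
#' @return Tibble with `id`, `call` (`"toxic"` / `"abstain"`), `n_hits`,
#'   `best_evalue` (NA when no hit).
#' @export
motif_only_predict <- function(ds, motifs, evalue_max = 10) {
  .check_dataset(ds)
  hits <- .scan_many(ds$seq, motifs, evalue_max)
  tibble(
    id = ds$id,
    call = ifelse(vapply(hits, nrow, integer(1)) > 0L, "toxic", "abstain"),
    n_hits = vapply(hits, nrow, integer(1)),
    best_evalue = vapply(hits, function(h) {
      if (nrow(h)) min(h$evalue) else NA_real_
    }, numeric(1)))
}

#' Write motifs in MEME minimal text format
#'
#' The produced file is consumable by external MAST.
#'
#' @param motifs A `motif_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme_motifs <- function(motifs, path) {
  stopifnot(inherits(motifs, "motif_set"))
  con <- file(path, "w")
  on.exit(close(con))
  bg <- attr(motifs, "background") %||% .MOTIF_BACKGROUND
  writeLines(c("MEME version 4", "",
               "ALPHABET= ACDEFGHIKLMNPQRSTVWY", "",
               "Background letter frequencies",
               paste(paste(.AA, format(bg, nsmall = 2)), collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s %s", m$id, m$consensus), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= %g",
      m$width, m$n_sites, 1 / m$enrichment), con)
    for (p in seq_len(m$width)) {
      writeLines(paste(sprintf("%.6f", m$pwm[p, ]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal text format
#'
#' @param path Path to a MEME-format motif file.
#' @return A `motif_set`.
#' @export
read_meme_motifs <- function(path) {
  if (!file.exists(path)) .stop_io(sprintf("cannot read motif file: %s", path))
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^MOTIF ", lines)
  if (length(starts) == 0L) .stop_format(sprintf("no MOTIF blocks in %s", path))
  motifs <- lapply(starts, function(i) {
    hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    mat_i <- i + 1L
    while (mat_i <= length(lines) &&
           !grepl("^letter-probability matrix", lines[mat_i])) {
      mat_i <- mat_i + 1L
    }
    if (mat_i > length(lines)) .stop_format("motif block missing probability matrix")
    w <- as.integer(sub(".*w= *([0-9]+).*", "\\1", lines[mat_i]))
    nsites <- suppressWarnings(as.integer(sub(".*nsites= *([0-9]+).*", "\\1",
                                              lines[mat_i])))
    pwm <- do.call(rbind, lapply(lines[(mat_i + 1L):(mat_i + w)], function(l) {
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    }))
    if (ncol(pwm) != 20L) .stop_format("motif matrix must have 20 columns")
    colnames(pwm) <- .AA
    structure(list(id = hdr[2],
                   consensus = if (length(hdr) >= 3L) hdr[3] else
                     paste(.AA[apply(pwm, 1L, which.max)], collapse = ""),
                   width = w, pwm = pwm / rowSums(pwm),
                   enrichment = NA_real_,
                   n_sites = if (is.na(nsites)) 0L else nsites,
                   n_pos = NA_integer_, n_neg = NA_integer_),
              class = "pep_motif")
  })
  structure(motifs, class = "motif_set", background = .MOTIF_BACKGROUND,
            seed = NA_integer_)
}

#' Run external MEME/MAST (optional adapter)
#'
#' Writes the positive set and the query set to FASTA, runs the external
#' `meme` binary on the positives and `mast` on the queries, and parses the
#' MAST hit list into hit records. Requires the MEME suite on the PATH (or
#' explicit binary paths); when the binaries are absent a
#' `peptox_feature_unavailable` error is raised with guidance.
#'
#' @param pos Positive (toxic) training dataset.
#' @param query Dataset to scan.
#' @param meme,mast Paths to the `meme` and `mast` binaries.
#' @param n_motifs Number of motifs MEME should report.
#' @param min_width,max_width Motif width range.
#' @param evalue_max MAST sequence E-value cutoff.
#' @return Tibble of hits: `id`, `motif`, `start`, `end`, `score`, `p_value`.
#' @export
run_external_meme_mast <- function(pos, query, meme = "meme", mast = "mast",
                                   n_motifs = 20L, min_width = 4L,
                                   max_width = 8L, evalue_max = 10) {
  .check_dataset(pos, "pos")
  .check_dataset(query, "query")
  meme_bin <- Sys.which(meme)
  mast_bin <- Sys.which(mast)
  if (meme_bin == "" || mast_bin == "") {
    abort(paste("external tools unavailable: meme/mast binaries not found;",
                "install the MEME suite or use discover_motifs()/scan_motifs()"),
          class = "peptox_feature_unavailable")
  }
  dir <- tempfile("meme_mast_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  pos_fa <- file.path(dir, "pos.fa")
  query_fa <- file.path(dir, "query.fa")
  write_fasta(pos, pos_fa)
  write_fasta(query, query_fa)
  meme_out <- file.path(dir, "meme.txt")
  status <- system2(meme_bin,
                    c(pos_fa, "-protein", "-text", "-nmotifs", n_motifs,
                      "-minw", min_width, "-maxw", max_width, "-nostatus"),
                    stdout = meme_out, stderr = FALSE)
  if (status != 0L || !file.size(meme_out)) {
    abort("MEME run failed; inspect the input FASTA", class = "peptox_adapter_error")
  }
  hits_out <- file.path(dir, "mast_hits.txt")
  status <- system2(mast_bin, c(meme_out, query_fa, "-hit_list",
                                "-ev", format(evalue_max), "-nostatus"),
                    stdout = hits_out, stderr = FALSE)
  if (status != 0L) {
    abort("MAST run failed; inspect the MEME output", class = "peptox_adapter_error")
  }
  lines <- grep("^#", readLines(hits_out, warn = FALSE),
                invert = TRUE, value = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble(id = character(), motif = character(), start = integer(),
                  end = integer(), score = numeric(), p_value = numeric()))
  }
  parsed <- tryCatch({
    f <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
    tibble(id = f[, 1], motif = f[, 3],
           start = abs(as.integer(f[, ncol(f) - 3L])),
           end = as.integer(f[, ncol(f) - 2L]),
           score = as.numeric(f[, ncol(f) - 1L]),
           p_value = as.numeric(f[, ncol(f)]))
  }, error = function(e) NULL)
  if (is.null(parsed)) {
    abort(paste0("could not parse MAST hit list; first line: ", lines[1]),
          class = "peptox_adapter_error")
  }
  parsed
}
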