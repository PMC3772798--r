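# Seeded synthetic peptide generator. Residues are sampled i.i.d. from
# class-specific weight tables (lengths uniform over a range); an optional
# exact motif is planted into a uniformly chosen window of each positive
# peptide with a fixed probability. All positional signal comes from the
# planted motif; all compositional signal from the weight tables.

#' Default class residue-weight tables
#'
#' The non-toxic table boosts Ala, Phe, Ile, Val, Leu and Lys above the
#' uniform 0.05 and depresses Cys to 0.01. The toxic table is *derived* from
#' the non-toxic table so that, after motif planting is accounted for, the
#' expected per-peptide composition of the two classes differs only in the
#' target residues: Cys, His, Asn, Pro up in toxics; Ala, Phe, Ile, Val down.
#' Planting a width-`w` motif with probability `q` rescales every non-motif
#' residue's expected composition in positives by `s = 1 - q * w * E[1/L]`
#' and adds `q * E[1/L]` per motif occurrence of a residue, so the matched
#' (non-target) residues use `w_toxic = (w_nontoxic - q * E[1/L] * c_r) / s`
#' where `c_r` counts the residue in the motif. Cys keeps the strictly
#' largest toxic-table weight.
#'
#' @param min_len,max_len Peptide length range (uniform).
#' @param motif Planted motif (residue string) whose composition is netted
#'   out of the toxic table.
#' @param motif_prob Planting probability.
#' @return List with numeric weight vectors `toxic` and `nontoxic`, each
#'   named by residue and summing to 1.
#' @export
default_bias_tables <- function(min_len = 5L, max_len = 35L,
                                motif = "CCKHC", motif_prob = 0.6) {
  nontoxic <- setNames(rep(0.035, 20L), .AA)
  nontoxic[c("A", "F", "I", "V", "L", "K")] <- c(0.100, 0.085, 0.085, 0.090,
                                                 0.100, 0.075)
  nontoxic["C"] <- 0.010
  nontoxic <- nontoxic / sum(nontoxic)

  w <- nchar(motif)
  m1 <- mean(1 / (min_len:max_len))          # E[1/L] for uniform lengths
  s <- 1 - motif_prob * w * m1               # survival share of non-motif residues
  if (s <= 0) .stop_domain("motif planting would dominate the peptides entirely")
  cnt <- table(factor(strsplit(motif, "", fixed = TRUE)[[1]], levels = .AA))
  cnt <- setNames(as.numeric(cnt), .AA)

  target_pos <- c("C", "H", "N", "P")
  target_neg <- c("A", "F", "I", "V")
  matched <- setdiff(.AA, c(target_pos, target_neg))

  toxic <- setNames(numeric(20L), .AA)
  toxic[matched] <- (nontoxic[matched] - motif_prob * m1 * cnt[matched]) / s
  toxic[target_neg] <- 0.016
  toxic["C"] <- 0.13
  # split the remaining mass so His, Asn and Pro reach the same *effective*
  # composition e in positives (His also receives motif occurrences)
  rem <- 1 - sum(toxic[c(matched, target_neg, "C")])
  e <- (rem * s + motif_prob * m1 * sum(cnt[c("H", "N", "P")])) / 3
  toxic[c("H", "N", "P")] <- (e - motif_prob * m1 * cnt[c("H", "N", "P")]) / s

  if (any(toxic < 0)) .stop_domain("derived toxic weights are not all non-negative")
  if (toxic["C"] <= max(toxic[setdiff(.AA, "C")])) {
    .stop_domain("toxic-table Cys weight must remain strictly maximal")
  }
  list(toxic = toxic, nontoxic = nontoxic)
}

#' Generator configuration
#'
#' @param n_pos,n_neg Number of toxic / non-toxic peptides.
#' @param min_len,max_len Length range (uniform; `max_len` at most 35 so
#'   generated data passes [filter_dataset()] unchanged).
#' @param toxic_weights,nontoxic_weights Named 20-entry weight tables summing
#'   to 1; defaults from [default_bias_tables()].
#' @param motif Planted motif (`NULL` or `""` disables planting); must fit
#'   the shortest peptide when `motif_prob > 0`.
#' @param motif_prob Probability a positive peptide carries the motif.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_pos = 500L, n_neg = 500L, min_len = 5L,
                             max_len = 35L, toxic_weights = NULL,
                             nontoxic_weights = NULL, motif = "CCKHC",
                             motif_prob = 0.6, seed = 1L) {
  if (n_pos < 1L || n_neg < 1L) .stop_domain("n_pos and n_neg must be positive")
  if (min_len < 1L || max_len < min_len) .stop_domain("invalid length range")
  if (max_len > 35L) .stop_domain("max_len must not exceed 35")
  if (motif_prob < 0 || motif_prob > 1) .stop_domain("motif_prob must be in [0, 1]")
  if (is.null(motif)) motif <- ""
  if (nzchar(motif)) {
    motif <- .check_seq(motif, 1L, "motif")
    if (motif_prob > 0 && nchar(motif) > min_len) {
      .stop_domain(sprintf(
        "motif of width %d cannot be planted: longer than min_len=%d",
        nchar(motif), min_len))
    }
  }
  if (is.null(toxic_weights) || is.null(nontoxic_weights)) {
    tabs <- default_bias_tables(min_len, max_len,
                                if (nzchar(motif)) motif else "CCKHC",
                                if (nzchar(motif)) motif_prob else 0)
    if (is.null(toxic_weights)) toxic_weights <- tabs$toxic
    if (is.null(nontoxic_weights)) nontoxic_weights <- tabs$nontoxic
  }
  for (wt in list(toxic_weights, nontoxic_weights)) {
    if (length(wt) != 20L || any(wt < 0) || abs(sum(wt) - 1) > 1e-9) {
      .stop_domain("weight tables must be 20 non-negative values summing to 1")
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 toxic_weights = setNames(as.numeric(toxic_weights), .AA),
                 nontoxic_weights = setNames(as.numeric(nontoxic_weights), .AA),
                 motif = motif, motif_prob = motif_prob,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic labelled peptide benchmark
#'
#' Lengths are uniform over the configured range; residues are i.i.d. from
#' the class weight table; with the planting probability, the motif
#' overwrites a uniformly chosen window of a positive peptide. Identical
#' configurations (including seed) generate byte-identical datasets.
#'
#' @param config A [generator_config()].
#' @return List with dataset tibbles `pos` (labelled toxic) and `neg`
#'   (labelled nontoxic).
#' @export
#' @examples
#' sim <- generate_dataset(generator_config(n_pos = 5, n_neg = 5, seed = 42))
#' sim$pos
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  lens <- seq(config$min_len, config$max_len)

  gen <- function(n, weights, plant_motif) {
    L <- if (length(lens) == 1L) rep.int(lens, n)
         else sample(lens, n, replace = TRUE)
    seqs <- vapply(L, function(l) {
      paste(sample(.AA, l, replace = TRUE, prob = weights), collapse = "")
    }, character(1))
    if (plant_motif) {
      w <- nchar(config$motif)
      plant <- runif(n) < config$motif_prob & nchar(seqs) >= w
      for (i in which(plant)) {
        start <- sample.int(nchar(seqs[i]) - w + 1L, 1L)
        substr(seqs[i], start, start + w - 1L) <- config$motif
      }
    }
    seqs
  }

  # chance collisions are regenerated so each class is duplicate-free and the
  # output passes filter_dataset() unchanged
  gen_unique <- function(n, weights, plant_motif) {
    seqs <- gen(n, weights, plant_motif)
    for (round in 1:100) {
      dup <- which(duplicated(seqs))
      if (length(dup) == 0L) return(seqs)
      seqs[dup] <- gen(length(dup), weights, plant_motif)
    }
    .stop_domain("could not generate the requested number of unique peptides")
  }

  planting <- nzchar(config$motif) && config$motif_prob > 0
  pos_seq <- gen_unique(config$n_pos, config$toxic_weights, planting)
  neg_seq <- gen_unique(config$n_neg, config$nontoxic_weights, FALSE)

  list(
    pos = peptide_dataset(pos_seq, sprintf("tox%04d", seq_len(config$n_pos)),
                          "toxic"),
    neg = peptide_dataset(neg_seq, sprintf("ntx%04d", seq_len(config$n_neg)),
                          "nontoxic"))
}
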