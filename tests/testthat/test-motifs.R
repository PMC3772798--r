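test_that("discovery recovers the planted motif as the top seed", {
  sim <- sim_medium(150, seed = 6)
  motifs <- discover_motifs(sim$pos, sim$neg, seed = 1)
  expect_s3_class(motifs, "motif_set")
  expect_lte(length(motifs), 20L)
  top <- motifs[[1]]$consensus
  # the top seed is the planted motif, a substring of it, or a superstring
  expect_true(grepl(top, "CCKHC", fixed = TRUE) || grepl("CCKHC", top, fixed = TRUE))
  expect_gt(motifs[[1]]$enrichment, 10)
})

test_that("pwm rows are probability distributions", {
  sim <- sim_medium(100, seed = 6)
  motifs <- discover_motifs(sim$pos, sim$neg, n_motifs = 5, seed = 1)
  for (m in motifs) {
    expect_equal(unname(rowSums(m$pwm)), rep(1, m$width), tolerance = 1e-9)
    expect_true(all(m$pwm >= 0))
  }
})

test_that("no enriched motif is reported when classes are identical", {
  ds <- peptide_dataset(random_peptides(40, 8, 20), label = "toxic")
  motifs <- discover_motifs(ds, ds, seed = 1)
  expect_length(motifs, 0L)
})

test_that("the n_motifs cap and the minimum-positives precondition hold", {
  sim <- sim_medium(100, seed = 6)
  expect_lte(length(discover_motifs(sim$pos, sim$neg, n_motifs = 1, seed = 1)), 1L)
  few <- peptide_dataset(random_peptides(5, 10, 20), label = "toxic")
  expect_error(discover_motifs(few, sim$neg, seed = 1),
               class = "peptox_discovery_error")
})

test_that("an exact consensus match is a highly significant hit at its offset", {
  sim <- sim_medium(150, seed = 6)
  motifs <- discover_motifs(sim$pos, sim$neg, n_motifs = 3, seed = 1)
  top <- motifs[[1]]
  seq <- paste0("LLLL", top$consensus, "LLLL")
  hits <- scan_motifs(seq, motifs, evalue_max = 10)
  best <- hits[hits$motif == top$id, ]
  expect_gte(nrow(best), 1L)
  expect_equal(best$start[1], 5L)
  expect_lt(best$evalue[1], 1)
  # consensus attains the maximal achievable match score for its own pwm
  expect_equal(best$score[1],
               sum(log2(apply(top$pwm, 1, max) / 0.05)), tolerance = 1e-2)
})

test_that("hit lists are nested across E-value cutoffs", {
  sim <- sim_medium(100, seed = 6)
  motifs <- discover_motifs(sim$pos, sim$neg, n_motifs = 10, seed = 1)
  set.seed(31)
  for (s in random_peptides(10, 10, 30)) {
    loose <- scan_motifs(s, motifs, evalue_max = 10)
    tight <- scan_motifs(s, motifs, evalue_max = 1e-7)
    key <- function(h) paste(h$motif, h$start)
    expect_true(all(key(tight) %in% key(loose)))
    expect_true(all(loose$evalue > 0))
  }
})

test_that("the DP null p-value matches exhaustive window enumeration", {
  # small synthetic motif so 20^w enumeration is exact and cheap
  pwm <- matrix(1, nrow = 3, ncol = 20, dimnames = list(NULL, amino_acids()))
  pwm[1, "C"] <- 50; pwm[2, "K"] <- 30; pwm[3, "H"] <- 10
  pwm <- pwm / rowSums(pwm)
  motif <- structure(list(id = "m1", consensus = "CKH", width = 3L, pwm = pwm,
                          enrichment = 10, n_sites = 10, n_pos = 10, n_neg = 0),
                     class = "pep_motif")
  tab <- peptox:::.motif_tables(motif)
  S <- tab$S
  grid <- expand.grid(a = 1:20, b = 1:20, c = 1:20)
  all_scores <- S[1, grid$a] + S[2, grid$b] + S[3, grid$c]
  for (obs in quantile(all_scores, c(0, .25, .5, .9, 1), type = 1)) {
    exact <- mean(all_scores >= obs)
    expect_equal(peptox:::.motif_pvalue(as.integer(obs), tab), exact,
                 tolerance = 1e-12)
  }
})

test_that("motif-only prediction abstains without hits and never un-abstains on tightening", {
  sim <- sim_medium(120, seed = 6)
  motifs <- discover_motifs(sim$pos, sim$neg, seed = 1)
  planted <- peptide_dataset(paste0("AAAA", "CCKHC", "AAAA"), "planted")
  expect_equal(motif_only_predict(planted, motifs, 10)$call, "toxic")

  ds <- dplyr::bind_rows(sim$pos[1:40, ], sim$neg[1:40, ])
  loose <- motif_only_predict(ds, motifs, 10)$call
  tight <- motif_only_predict(ds, motifs, 0.01)$call
  expect_true(all(!(loose == "abstain" & tight == "toxic")))
  expect_true(any(tight == "abstain"))
})

test_that("motif sets round-trip through MEME minimal format", {
  sim <- sim_medium(100, seed = 6)
  motifs <- discover_motifs(sim$pos, sim$neg, n_motifs = 4, seed = 1)
  path <- tempfile(fileext = ".meme")
  withr::defer(unlink(path))
  write_meme_motifs(motifs, path)
  expect_match(readLines(path, n = 1), "MEME version")
  back <- read_meme_motifs(path)
  expect_length(back, length(motifs))
  expect_equal(back[[1]]$consensus, motifs[[1]]$consensus)
  expect_equal(back[[1]]$pwm, motifs[[1]]$pwm, tolerance = 1e-4,
               ignore_attr = TRUE)
  # scanning with reloaded motifs reproduces calls
  probe <- peptide_dataset(c(paste0("LL", motifs[[1]]$consensus, "LL"),
                             strrep("W", 12)))
  expect_equal(motif_only_predict(probe, back, 1)$call,
               motif_only_predict(probe, motifs, 1)$call)
})

test_that("the external MEME/MAST adapter degrades cleanly", {
  sim <- sim_medium(30, seed = 6)
  if (Sys.which("meme") == "" || Sys.which("mast") == "") {
    expect_error(run_external_meme_mast(sim$pos, sim$neg),
                 class = "peptox_feature_unavailable")
  } else {
    hits <- run_external_meme_mast(sim$pos, sim$pos[1:5, ])
    expect_s3_class(hits, "tbl_df")
  }
})
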