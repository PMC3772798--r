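test_that("position frequencies count peptides reaching each position", {
  ds <- peptide_dataset("AA")
  f <- position_frequency(ds, "mono", max_len = 5)
  expect_equal(f["A", 1], 100)
  expect_equal(f["A", 2], 100)
  expect_equal(sum(f), 200)

  ds2 <- peptide_dataset(c("AC", "AD"))
  f2 <- position_frequency(ds2, "mono", max_len = 5)
  expect_equal(f2["A", 1], 100)
  expect_equal(f2["C", 2], 50)
  expect_equal(f2["D", 2], 50)

  f3 <- position_frequency(peptide_dataset("ACD"), "dipep", max_len = 5)
  expect_equal(f3["AC", 1], 100)
  expect_equal(f3["CD", 2], 100)
  expect_equal(dim(f3), c(400L, 4L))
})

test_that("reached columns are normalized to 100", {
  set.seed(21)
  ds <- peptide_dataset(random_peptides(30, 5, 20))
  f <- position_frequency(ds, "mono", max_len = 35)
  counts <- attr(f, "position_counts")
  sums <- colSums(f)
  expect_equal(unname(sums[counts > 0]), rep(100, sum(counts > 0)), tolerance = 1e-9)
  expect_true(all(sums[counts == 0] == 0))
})

test_that("over-length records are rejected with a pointer to the filter", {
  ds <- peptide_dataset(strrep("A", 36))
  expect_error(position_frequency(ds, "mono", 35), "filter_dataset",
               class = "peptox_domain_error")
})

test_that("the quantitative matrix is the positive minus negative frequency table", {
  qm <- build_qm(peptide_dataset(c("AC", "AD"), label = "toxic"),
                 peptide_dataset(c("CC", "CD"), label = "nontoxic"),
                 "mono", max_len = 2)
  expect_equal(qm$cells["A", 1], 100)
  expect_equal(qm$cells["C", 1], -100)
  expect_equal(qm$cells["C", 2], 0)
  expect_equal(qm$cells["D", 2], 0)
  expect_true(all(qm$cells >= -100 & qm$cells <= 100))
})

test_that("self-subtraction yields zero and class swap negates every cell", {
  sim <- sim_medium(40)
  expect_true(all(build_qm(sim$pos, sim$pos, "mono")$cells == 0))
  fwd <- build_qm(sim$pos, sim$neg, "dipep")
  rev <- build_qm(sim$neg, sim$pos, "dipep")
  expect_equal(fwd$cells, -rev$cells)
})

test_that("qm scoring is the cumulative sum of positional cells", {
  qm <- build_qm(peptide_dataset(c("AC", "AD"), label = "toxic"),
                 peptide_dataset(c("CC", "CD"), label = "nontoxic"),
                 "mono", max_len = 2)
  expect_equal(qm_score("AC", qm), 100)   # cell(A,1) + cell(C,2) = 100 + 0
  zero <- qm
  zero$cells[] <- 0
  expect_equal(qm_score(c("AC", "CD"), zero), c(0, 0))
  expect_error(qm_score(strrep("A", 3), qm), class = "peptox_domain_error")
})

test_that("truncating the last residue removes exactly its positional cell", {
  sim <- sim_medium(40)
  qm <- build_qm(sim$pos, sim$neg, "mono")
  set.seed(22)
  for (s in random_peptides(10, 6, 20)) {
    last <- substr(s, nchar(s), nchar(s))
    expect_equal(qm_score(s, qm) - qm_score(substr(s, 1, nchar(s) - 1), qm),
                 qm$cells[last, nchar(s)])
  }
})

test_that("qm scores match an independent per-position lookup oracle", {
  sim <- sim_medium(60)
  qm <- build_qm(sim$pos, sim$neg, "mono")
  long <- tidy(qm)  # independent lookup route: long-format join
  set.seed(23)
  for (s in random_peptides(50, 5, 35)) {
    ch <- strsplit(s, "")[[1]]
    oracle <- sum(vapply(seq_along(ch), function(p) {
      long$value[long$element == ch[p] & long$position == p]
    }, numeric(1)))
    expect_equal(qm_score(s, qm), oracle, tolerance = 1e-12)
  }
})

test_that("qm classification uses >= threshold with mode-specific defaults", {
  expect_equal(qm_classify(25), "toxic")            # mono default 20
  expect_equal(qm_classify(20), "toxic")            # boundary inclusive
  expect_equal(qm_classify(19.99), "nontoxic")
  dq <- structure(list(mode = "dipep"), class = "quant_matrix")
  expect_equal(qm_classify(4.9, dq), "nontoxic")    # dipep default 5
  expect_equal(qm_classify(5, dq), "toxic")
})

test_that("position extremes pick argmax/argmin with alphabetical tie-break", {
  zero <- build_qm(peptide_dataset("AA"), peptide_dataset("AA"), "mono", 3)
  ex <- position_extremes(zero)
  expect_true(all(ex$max_element == "A"))
  expect_true(all(ex$max_score == 0 & ex$min_score == 0))

  qm <- build_qm(peptide_dataset(c("AC", "AD"), label = "toxic"),
                 peptide_dataset(c("CC", "CD"), label = "nontoxic"),
                 "mono", max_len = 2)
  ex2 <- position_extremes(qm)
  expect_equal(ex2$max_element[1], "A")
  expect_equal(ex2$max_score[1], 100)
  expect_equal(ex2$min_element[1], "C")
  expect_equal(ex2$min_score[1], -100)
})

test_that("cysteine dominates per-position maxima on default fixtures", {
  sim <- sim_medium(250, seed = 5)
  qm <- build_qm(sim$pos, sim$neg, "mono")
  ex <- position_extremes(qm)
  expect_gt(mean(ex$max_element == "C"), 0.5)
})

test_that("substitution reports quantify per-position gains", {
  qm <- build_qm(peptide_dataset(c("AC", "AD"), label = "toxic"),
                 peptide_dataset(c("CC", "CD"), label = "nontoxic"),
                 "mono", max_len = 2)
  rep_cc <- qms_report("CC", qm, "maximize")
  expect_equal(rep_cc$suggestion[1], "A")
  expect_equal(rep_cc$delta[1], qm$cells["A", 1] - qm$cells["C", 1])
  expect_equal(attr(rep_cc, "total_score"), qm_score("CC", qm))

  # applying every maximizing suggestion attains the position-extremes path
  best <- paste(rep_cc$suggestion, collapse = "")
  expect_equal(qm_score(best, qm), sum(position_extremes(qm)$max_score[1:2]))
  # an already per-position-optimal peptide has all gains 0
  expect_true(all(qms_report(best, qm, "maximize")$delta == 0))
})

test_that("replacing a residue with the column max never decreases the score", {
  sim <- sim_medium(40)
  qm <- build_qm(sim$pos, sim$neg, "mono")
  ex <- position_extremes(qm)
  set.seed(24)
  for (s in random_peptides(10, 5, 20)) {
    p <- sample(nchar(s), 1)
    mutated <- s
    substr(mutated, p, p) <- ex$max_element[p]
    expect_gte(qm_score(mutated, qm), qm_score(s, qm))
  }
})

test_that("quantitative matrices survive a TSV round trip", {
  sim <- sim_medium(30)
  qm <- build_qm(sim$pos, sim$neg, "mono")
  path <- tempfile(fileext = ".tsv")
  withr::defer(unlink(path))
  write_qm(qm, path)
  expect_match(readLines(path, n = 2)[2], "mode=mono")
  back <- read_qm(path)
  expect_equal(back$mode, qm$mode)
  expect_equal(back$max_len, qm$max_len)
  expect_equal(unname(back$cells), unname(qm$cells), tolerance = 1e-9)
  expect_equal(back$position_counts_pos, qm$position_counts_pos)
  probe <- random_peptides(5)
  expect_equal(qm_score(probe, back), qm_score(probe, qm), tolerance = 1e-9)
})
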