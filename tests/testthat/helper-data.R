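# Shared fixtures, built in code.

# a linearly separable toy: cysteine-only positives vs leucine-only negatives
toy_separable <- function(n = 10, len = 5) {
  list(
    pos = peptide_dataset(rep(strrep("C", len), n),
                          sprintf("p%02d", seq_len(n)), "toxic"),
    neg = peptide_dataset(rep(strrep("L", len), n),
                          sprintf("n%02d", seq_len(n)), "nontoxic"))
}

# random natural-residue peptides (uniform over the alphabet)
random_peptides <- function(n, min_len = 5, max_len = 20) {
  lens <- if (min_len == max_len) rep(min_len, n)
          else sample(min_len:max_len, n, replace = TRUE)
  vapply(lens, function(l) {
    paste(sample(amino_acids(), l, replace = TRUE), collapse = "")
  }, character(1))
}

write_tmp_fasta <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("pep", tmpdir = dir, fileext = ".fasta")
  writeLines(lines, path)
  path
}

# medium fixtures dataset shared by several suites (cheap to regenerate)
sim_medium <- function(n = 200, seed = 7) {
  generate_dataset(generator_config(n_pos = n, n_neg = n, seed = seed))
}
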