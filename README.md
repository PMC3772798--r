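# peptox

Sequence-only toxicity prediction for short peptides (≤ 35 residues).

Many venom-derived and bacterially-derived toxins are short, cysteine-rich
peptides, and anyone designing therapeutic peptides needs a fast in-silico
screen for accidental toxicity. `peptox` is a trainable R toolkit for that
problem: given labelled FASTA sets of toxic and non-toxic peptides it builds
classifiers from sequence alone, evaluates them with the field's standard
statistics, and turns them into design tools — which single mutation
detoxifies my peptide, and which region of my protein looks like a toxin?

It is aimed at computational biologists and peptide chemists; every
user-facing function takes and returns tidyverse-style tibbles, so results
chain straight into `dplyr`/`ggplot2` workflows.

## What is inside

* **Encoders** — amino acid composition (`Comp(i) = 100·R_i/N`, 20
  features), overlapping dipeptide composition (400 features), terminal-window
  composition (N*k*AAC / C*k*AAC) and one-hot binary terminal profiles
  (NT*k* / CT*k*, `k·20` features), plus a per-residue between-class
  composition comparison (Welch t tests, familywise-corrected dominance
  calls).
* **Quantitative matrices** — position-specific percent-frequency
  difference tables (positive − negative class; 20×35 residue-level or
  400×34 dipeptide-level). A peptide's score is the cumulative sum of its
  positional cells (toxic when ≥ 20 resp. 5); includes per-position
  extremes and substitution-gain reports.
* **SVM harness** — soft-margin kernel classification (libsvm via `e1071`)
  over any encoder, with the conventional `t/g/c/j` hyperparameter naming,
  signed decision scores (positive = toxic), threshold handling, and a
  **hybrid** rule that adds +5 to the score of any query carrying a
  toxic-peptide motif.
* **Motifs** — enumerative discovery of enriched ungapped k-mers in the
  toxic class (odds-ratio ranked, PWM-expanded), PWM scanning with exact
  DP null p-values and Bonferroni-style E-values, motif-only prediction
  with abstention, MEME-format persistence, optional external MEME/MAST
  adapter.
* **Evaluation** — stratified seeded k-fold CV, accuracy-maximizing
  threshold selection, sensitivity/specificity/accuracy/MCC, tie-aware
  ROC/AUC, PCP + coverage for abstaining predictors.
* **Design utilities** — exhaustive single-mutant enumeration (19·L) and
  ranking, greedy iterative design, sliding-window protein scanning with
  per-position score tracks and BED export, order-preserving batch
  prediction.
* **Synthetic benchmark** — a seeded generator planting the documented
  compositional biases (Cys/His/Asn/Pro-rich toxics vs
  Ala/Phe/Ile/Val/Leu/Lys-rich non-toxics) and an exact motif (`CCKHC`,
  60% of positives), so the whole pipeline is testable offline.
* **CLI** — `simulate`, `train`, `predict`, `evaluate`, `scan`, `design`,
  `qm-build`, `qm-score`, `discover-motifs` via the installed launcher
  (`system.file("cli", "peptox.R", package = "peptox")`); every run writes a
  provenance sidecar.

## Worked example

```r
library(peptox)

sim <- generate_dataset(generator_config(n_pos = 200, n_neg = 200, seed = 42))
cv  <- kfold_cv(sim$pos, sim$neg, model_config("DPC"), n_folds = 5, seed = 42)
cv
#> <cv_result> 5-fold stratified CV (seed 42)
#> <eval_report> n=400  threshold=-0.2331697
#>   Sensitivity 97.50  Specificity 96.00  Accuracy 96.75  MCC 0.935  AUC 0.997
```

The dipeptide-composition SVM recovers the planted class structure almost
perfectly: 97.5% of held-out toxic peptides and 96.0% of non-toxic peptides
are called correctly at the tuned threshold, with near-perfect ranking
(AUC 0.997). Motif discovery finds the planted signal:

```r
discover_motifs(sim$pos, sim$neg, n_motifs = 3, seed = 42)
#> <motif_set> 3 motif(s), uniform background 0.05
#>   motif_01  CCKH       width 4  enrichment 470.36  (108 pos / 0 neg peptides)
#>   motif_02  KHCC       width 4  enrichment 33.51  (15 pos / 0 neg peptides)
#>   motif_03  CCCC       width 4  enrichment 7.11  (3 pos / 0 neg peptides)
```

`motif_01` is the planted `CCKHC` core: it occurs in 108 positive and zero
negative peptides, an enrichment odds ratio of 470. The quantitative matrix
tells the same story per position — cysteine is the top-scoring residue
everywhere early in the peptide:

```r
head(position_extremes(build_qm(sim$pos, sim$neg, "mono")), 3)
#>   position max_element max_score min_element min_score
#> 1        1 C                  13 I                -8.5
#> 2        2 C                  21 V               -13
#> 3        3 C                  18 A               -10.5
```

And the design module answers "which single mutation makes this peptide
least toxic-looking":

```r
m <- train_model(sim$pos, sim$neg, model_config("DPC"), seed = 42)
head(rank_mutants("CCKHCAAAA", m, "minimize"), 4)
#>   mutant    position from  to     score  delta
#> 1 CIKHCAAAA        2 C     I     -0.510 -0.406
#> 2 CVKHCAAAA        2 C     V     -0.477 -0.373
#> 3 CFKHCAAAA        2 C     F     -0.450 -0.346
#> 4 CMKHCAAAA        2 C     M     -0.448 -0.345
```

Breaking the cysteine pair (C2→I/V/F/M) is exactly what drops the toxicity
score most — the `delta` column is the score change versus the parent.

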