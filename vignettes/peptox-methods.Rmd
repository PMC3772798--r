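---
title: "Predicting peptide toxicity from sequence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting peptide toxicity from sequence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Short peptides — venom components, bacterial toxin fragments, but also
therapeutic candidates — can be acutely toxic, and toxicity screening of
designed peptides is far cheaper in silico than in vivo. `peptox` implements
a classical sequence-only toxicity predictor for peptides of at most 35
residues: composition-based SVM classification, position-specific
quantitative matrices, motif scanning, and the design utilities built on top
of them (single-mutant ranking, sliding-window protein scanning). Everything
is trainable from any labelled FASTA pair, and a seeded synthetic generator
provides a self-contained benchmark.

## Sequence encoders

All encoders use one fixed feature order: the alphabetical one-letter codes
A, C, D, ..., Y. Serialized feature tables record the scheme in a comment
line.

* **AAC** — percent amino acid composition, $\mathrm{Comp}(i) = 100 R_i / N$
  for residue counts $R_i$ in a peptide of length $N$; 20 features summing
  to 100.
* **DPC** — dipeptide composition over the $N-1$ *overlapping* residue
  pairs, 400 features summing to 100. This is the standard reading of
  pair-composition; it captures local order that AAC discards.
* **NkAAC / CkAAC** — AAC of the first/last $k$ residues.
* **NTk / CTk** — one-hot binary profile of a terminal window: one 20-block
  per position (each block sums to exactly 1), $20k$ features. Injective on
  fixed-width windows, so it preserves residue order completely.

Peptides shorter than a requested terminal window are rejected, never
padded: padding would invent signal at the boundary. The cross-validation
harness drops such records with a logged warning.

`composition_comparison()` contrasts per-peptide AAC between classes with a
two-sided Welch (unequal-variance) t test per residue. Because 20 residues
are tested simultaneously and downstream consumers treat the dominance
column as a *set* of enriched residues, dominance calls are made on
Holm-adjusted p values (familywise error 0.05 across the family of 20
tests); the raw per-residue p value is reported alongside. With a raw 0.05
cut, roughly one null residue in two runs would be flagged by chance alone,
which makes the call set unreliable for exactly the purpose it serves.

## Quantitative matrices

`build_qm()` tabulates, per class, the percent frequency of each residue
(20 × 35, `mono`) or each overlapping dipeptide (400 × 34, `dipep`) at every
N-terminal-anchored position, and subtracts the negative-class table from
the positive-class table. A query peptide's score is the cumulative sum of
its positional cells; scores at or above the threshold (defaults: 20 for
`mono`, 5 for `dipep`) are called toxic.

Two conventions are fixed and recorded in every serialized matrix:

* Positions are 1-based from the N-terminus; a peptide shorter than 35
  contributes only to the columns it reaches, and each column's denominator
  is the number of peptides reaching that position. This keeps every reached
  column normalized to 100 regardless of the length distribution. (The
  alternative — dividing by the total peptide count — conflates positional
  preference with length distribution.)
* No pseudocounts: cells are plain frequency differences, bounded in
  [−100, 100]. Absent residues contribute zero frequency.

Because positions are scored independently, per-position substitution
reports (`qms_report()`) are exact: applying every maximizing suggestion
attains the per-position maximum path reported by `position_extremes()`.

## The SVM harness

The margin optimizer is libsvm (via `e1071::svm`); the package owns the
parts that determine what the optimizer sees and how its output is read:
encoding scheme, label convention (toxic = positive decision side), the
per-class cost ratio `j`, raw decision-value scoring (no probability
calibration — all thresholds in this methodology live on the decision-value
scale), and thresholding with the inclusive convention score ≥ threshold →
toxic. Features are passed unscaled: composition features already share a
common percent scale, and binary profiles are 0/1.

The default configuration is the headline dipeptide model of this
methodology: RBF kernel, γ = 0.001, C = 5, balanced class cost, threshold
−0.4. Absolute decision-value thresholds do not transfer between SVM
implementations, so `kfold_cv()` re-tunes the threshold rather than trusting
a preset.

**Where the threshold is tuned.** `threshold_select()` sweeps
min(score)..max(score) at a 0.1 grid and maximizes accuracy, breaking ties
by the smallest |sensitivity − specificity| and then by the lower threshold.
An obvious leakage-safe choice would be to tune on the pooled training-side
(resubstitution) scores of the CV folds. In practice that choice is
systematically miscalibrated here: the RBF SVM separates its own training
records with a wide margin (training scores cluster beyond ±1), so the
accuracy-maximizing threshold on training scores is an entire interval and
the deterministic tie-break parks it at the negative margin edge — a region
that held-out negatives routinely cross. `kfold_cv()` therefore selects the
single pooled threshold on the pooled *held-out* scores, the convention
under which per-model thresholds are conventionally reported alongside
cross-validated performance. This makes the reported accuracy mildly
optimistic (one free parameter chosen on the evaluation scores); pass a
fixed `threshold` to `kfold_cv()` to remove that freedom.

## Motifs and the hybrid rule

Full EM-based motif discovery is deliberately not re-implemented. The
in-package stand-in is enumerative and fully testable: every ungapped k-mer
(widths 4–8) occurring in the toxic peptides is scored by its peptide-level
enrichment odds ratio against the non-toxic peptides (+0.5 continuity
correction); seeds are picked greedily by decreasing odds, skipping
candidates that overlap an already-chosen seed on all but one aligned
position; each seed becomes a position probability matrix from its exact
matches with +1 pseudocount per cell. An adapter to external MEME/MAST
binaries is provided for fidelity work and degrades to a clean error when
the suite is absent.

Scanning slides each PWM over the query; the window match score is
$\sum_p \log_2(\mathrm{pwm}[p, x_p] / 0.05)$ against a uniform background
(0.05 per residue, recorded in motif files). The p-value is *exact* under
the i.i.d. uniform null: the null score distribution is built by dynamic
programming over positions with log-odds integerized at a granularity of
10⁻³ (the observed score is integerized identically, so the DP agrees with
brute-force enumeration of all 20^w windows). The E-value is
Bonferroni-style: p-value × total windows scanned across all motifs in the
query. Hit lists are therefore nested across E-value cutoffs.

The hybrid rule adds a constant +5 to the SVM decision score of any query
carrying a motif hit, which forces a toxic call at any threshold in the
usual decision-value range. One consequence of the Bonferroni-style E-value
needs care: at the permissive exploratory cutoff E ≤ 10 a query of L
residues is *expected* to collect several background-level window hits, so
boosting at E ≤ 10 would misflag a material fraction of genuinely non-toxic
queries. (Sequence-level E-values of external scanners aggregate over a
database and are not comparable.) The hybrid default is therefore
E ≤ 0.01 — about a 1% familywise chance of a spurious hit per query — while
`scan_motifs()` keeps E ≤ 10 as its exploratory default. Both are plain
arguments.

## Evaluation

Sensitivity, specificity and accuracy are percentages; MCC uses the
standard product-denominator form with the MCC = 0 convention when any
factor of the denominator is zero. ROC curves sweep all distinct scores as
thresholds with tied scores grouped into single steps and trapezoid
integration, which equals the Mann–Whitney probability with ties counted
half. Cross-validation is stratified, seeded, and reported from pooled
held-out scores (per-fold reports are also emitted and their counts sum
exactly to the pooled counts); pooling keeps the report consistent with the
single selected threshold. For abstaining predictors, coverage is the
percent of queries receiving any call and PCP the percent correct among
them.

## The synthetic benchmark

`generate_dataset()` emulates the compositional structure reported for real
toxin/non-toxin collections: cysteine-rich toxic peptides (disulfide-dense
venom scaffolds) with His/Asn/Pro enrichment, against non-toxic peptides
enriched in Ala/Phe/Ile/Val/Leu/Lys and depleted in Cys. Lengths are
uniform on 5–35; residues are i.i.d. from a class weight table; an exact
motif (default `CCKHC`, probability 0.6, positives only) overwrites a
uniformly chosen window. All positional signal comes from the planted
motif and all compositional signal from the weight tables, so each
method's signal source is explicit and can be ablated independently.
Chance duplicate sequences are regenerated, so the output always passes
`filter_dataset()` unchanged.

The default weight tables are stated constants, not values fitted to any
published figure. The non-toxic table is fixed directly (A 0.100, L 0.100,
V 0.090, F 0.085, I 0.085, K 0.075, C 0.010, all others 0.035). The toxic
table is *derived* so that the realized class difference is confined to the
eight target residues: planting a width-w motif with probability q rescales
every non-motif residue's expected per-peptide composition by
$s = 1 - qw\,\mathbb{E}[1/L]$ and adds $q\,\mathbb{E}[1/L]$ per motif
occurrence, so non-target residues use $w_t = (w_n - q\,\mathbb{E}[1/L]\,
c_r)/s$ (with $c_r$ the residue's count in the motif), the four negative
targets are fixed at 0.016, Cys at 0.13 (kept strictly maximal in the
table), and His/Asn/Pro split the remaining mass to equal effective
enrichment. Without this netting-out, Leu/Lys and every neutral residue
would acquire spurious class differences through the motif overwrite, and a
composition analysis would flag residues the design never intended to
separate.

What the generator does *not* emulate: phylogenetic redundancy between
related toxins, cysteine-bridge topology (positional pairing of Cys),
length–class correlation, and any positional structure beyond the single
planted motif. Passing benchmarks on this generator therefore demonstrates
correct machinery and calibration, not field performance on curated toxin
databases — reproducing published absolute accuracies requires the original
training collections.

## Numerical choices and problem sizes

* Score-at-threshold is toxic everywhere (classifier, QM, scan windows).
* Argmax/argmin ties in matrices resolve alphabetically; threshold-sweep
  ties resolve toward balance, then the lower threshold.
* Motif log-odds are integerized at 10⁻³ for the exact null DP; reported
  match scores keep full precision.
* MCC denominators are computed in double precision (no integer overflow).
* The test-suite and acceptance runs use 500 + 500 peptides for
  cross-validated benchmarks, 1000 + 1000 for the chance-calibration and
  composition-recovery checks, and 300 + 300 for the motif trade-off sweep —
  sizes at which every check completes in seconds to a couple of minutes on
  a single core while keeping binomial noise well inside the asserted
  margins.

## Known limitations

* Enumerative discovery only finds exact (ungapped, unmutated) seeds;
  degenerate motifs are represented only through the pseudocount.
* Thresholds tuned on pooled CV scores carry one parameter of optimism; an
  untouched external validation split is the clean alternative when data
  allows.
* Decision scores are uncalibrated margins — comparable within one model
  only.
* The 35-residue cap is structural (matrix depth, dataset filter); proteins
  are handled through windowed scanning, not whole-sequence scoring.
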