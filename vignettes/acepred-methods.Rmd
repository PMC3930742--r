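---
title: "Methods: sequence features and evaluation protocol in acepred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence features and evaluation protocol in acepred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acepred)
```

`acepred` predicts N-epsilon lysine acetylation from sequence alone. This
vignette is the package's account of the science: the model, its
assumptions, the tunable parameters and their defaults, what the synthetic
generator does and does not emulate, and the design choices made where the
design was genuinely open.

## The unit of prediction

A candidate site is a lysine; its representation is the window of `2n + 1`
residues centered on it. The default half-width is `n = 10` (window 21),
the length at which window-scan experiments on curated acetylation data
plateau. Lysines within `n` residues of a terminus are kept, with
out-of-sequence positions padded by `X`; the pad symbol is inert in every
feature (it contributes neither to means, nor to transition pairs, nor to
positional counts), so terminal windows are scored on the residues they
actually have. Ambiguous residue letters (B, J, O, U, Z, `*`) are mapped to
`X` at ingestion, giving every downstream module a fixed 21-symbol
alphabet. Coordinates are 1-based in all user-facing I/O.

## Homology reduction

Near-identical windows inflate cross-validation estimates, so training
peptides are reduced by greedy clustering: windows joining the first
existing cluster whose representative they match at strictly more than 70%
ungapped positional identity. Because all windows share one fixed length,
identity needs no alignment, and a brute-force scan is exact — the
word-filter heuristics of general-purpose clustering tools are deliberately
not reproduced. Positives and negatives are reduced separately so labels
never merge. The scan order is the input order by default (an option sorts
lexicographically first); the choice only affects which cluster member
becomes representative, not the partition granularity.

## Feature blocks

**AAPP (physicochemical means).** Each AAindex scale maps residues to
numbers; a window's AAPP value is the mean over its non-pad residues.
Literal `NA` entries in a scale are replaced by 0 at parse time. Values are
min–max normalized to `[0, 1]` using bounds fitted *on the training fold
only* and clamped for unseen extremes — fitting bounds on all data would
leak test information. A constant scale normalizes to 0.5 everywhere and is
therefore uninformative by construction; feature selection discards it.

**CFS selection over AAPP.** With hundreds of AAindex scales most are
redundant. Subsets are scored by the standard CFS merit
(`k r̄_cf / sqrt(k + k(k-1) r̄_ff)`), with feature–class and
feature–feature association measured by absolute Pearson correlation
against the 0/1 label (point-biserial; a constant vector correlates 0).
The reference attribute evaluator in common use discretizes and uses
symmetric uncertainty instead; the continuous variant was chosen for
simplicity and is validated against exhaustive subset enumeration rather
than against any published selected-scale list. Search is best-first with
backtracking: expand the best open subset by single-feature additions, stop
after `stale_limit` (default 5) consecutive expansions that fail to improve
the global best. Ties break toward the lexicographically smallest index
set, so the search is deterministic. Selection runs inside each training
fold during cross-validation; the final model selects on its full training
set.

**TPM (adjacent-residue Markov score).** Class-conditional first-order
transition matrices are estimated from adjacent residue pairs with a
Laplace pseudocount (default 1, guaranteeing strictly positive entries and
finite log-ratios; rows with no observations fall back to uniform). A
window is scored by the natural-log likelihood ratio of its pair sequence
under the two chains. No initial-state term is included — the score is a
pure product of transitions — and the log base is immaterial because only
sign and ordering feed the classifier. Higher scores indicate the
acetylated class.

**PSSC (positional composition score).** Per-class positional residue
frequencies are estimated with a per-cell pseudocount (default 0.5). The
score matrix is `s[i, j] = (f_pos[i, j] - f_neg[i, j]) * r[j]`, where
`r[j]` is the information content (in bits) of position `j` computed from
the *pooled* training frequencies — the sequence-logo convention: sign
encodes class inclination, magnitude grows with positional conservation.
An alternative log-odds form `log2(f_pos/f_neg) * r[j]` is available via
`pssc_mode = "logodds"`. No significance thresholding is applied to
individual cells. The central position scores exactly 0 (both classes have
K there), and pad positions score 0.

## The classifier

Features — selected AAPP columns, `tpm_score`, `pssc_score` — feed a
logistic regression fitted by maximizing the Bernoulli log-likelihood
(Newton/IRLS with step-halving; tolerance `1e-8`, at most 100 iterations).
A ridge penalty on non-intercept weights (default `1e-6`, intercept never
penalized) exists purely for numerical stability under near-separable
synthetic data; `l2 = 0` gives the pure maximum-likelihood fit and the
implementation is checked against R's reference IRLS to `1e-6` in
predicted probability. The decision threshold defaults to 0.5 with ties
called positive — the natural operating point for a balanced-training
logistic model.

## Evaluation protocol

Real acetylation data are heavily unbalanced, which skews threshold
metrics. The protocol therefore draws a negative set equal in size to the
positive set (without replacement), runs stratified k-fold
cross-validation (default `k = 10`), and repeats the draw 10 times,
reporting per-iteration metrics with mean and standard deviation. Inside
every fold the *entire* pipeline state — transition matrices, PSSC matrix,
normalization bounds, CFS selection — is re-estimated from the training
folds only. Metrics are Sn, Sp, Acc and MCC with a zero-denominator
convention of 0; both fold-averaged and pooled (micro-averaged) values are
reported, the fold/iteration average being the headline. A window-size
scan re-extracts windows at each half-width and runs the full protocol per
size.

Seeding: a master seed deterministically derives the fold seed and one
sampling seed per resampling iteration, so any single iteration is
re-runnable in isolation. The fold seed is shared across iterations;
consequently a negative pool exactly the size of the positive set (no
sampling freedom) yields identical iterations, and the between-iteration
spread isolates resampling variability — the quantity the repeated
protocol is meant to probe. Draws are kept in pool order so the sampled
*set*, not its ordering, determines the result.

## The synthetic generator

The generator emulates the compositional contrast reported for real
acetylated peptides: probability mass `delta` (default 0.3) is moved onto
K/R/G in positive windows and onto L/S/E in negative windows at offsets
±1…±7, over a uniform background, with the center fixed to K. Defaults —
2000 windows per class, `n = 10` — are the package's standard study
conditions; `delta = 0` is the null configuration (identical class
distributions), under which cross-validated accuracy calibrates to chance.
The uniform background was chosen because it makes analytic expectations
exact in tests; a natural-abundance background can be supplied. Sampling
is position-independent, which concentrates the planted signal in the
composition channel (PSSC) and lets ablation experiments attribute
performance; pair-level (TPM) signal arises only as a side effect of
composition shifts, and AAPP signal arises because the enriched residues
carry distinct values on the packaged scales. A separate Markov generator
simulates windows from explicit transition matrices for recovery tests;
its forced central K is excluded from recovery statistics by masking that
position to `X` (pads drop the adjacent pairs).

Whole-protein simulation plants positive windows into random background
proteins at about 2 sites per 300–600-residue protein — the site density
of curated acetylation data. This choice matters: planting much more
densely floods the unannotated-lysine pool with windows overlapping the
K-enriched flanks of planted sites, and these positive-looking "negatives"
distort window-length experiments. Even at realistic density the
window-scan accuracy surface beyond the true signal extent is nearly flat
(differences of well under two accuracy points), which is why the scan is
run under the full 10-iteration resampling protocol; single-iteration
scans pick their maximum essentially at random within the flat region.

What passing tests on these data do **not** show: real acetylation signal
is weaker (tens of percent accuracy above chance, not forty), positionally
correlated, and confounded by homology and by incomplete negative labels.
Synthetic results validate the machinery — leakage-free fold estimation,
correct formulas, qualitative feature ordering — not field performance.

## Numerical choices and degenerate inputs

* Min–max normalization: degenerate bounds map to 0.5; unseen extremes
  clamp to `[0, 1]`.
* Transition rows without observations (pseudocount 0) fall back to
  uniform `1/20`.
* Metric denominators of zero yield 0 for that metric.
* The empty CFS subset has merit 0; if search returns it (no informative
  scale), the AAPP block is dropped from the model rather than fitted on
  nothing.
* Model archives store numbers as hexadecimal floating point, so a
  reloaded model predicts bit-identically.
* Problem sizes in the shipped tests and acceptance script — 2000 windows
  per class for ablation, 1000 planted sites for the scan, 5000
  observations for coefficient recovery — were chosen as the smallest
  sizes at which the targeted effects are stable against sampling noise.

## Known limitations

* CFS uses Pearson association on a binary class; scales with purely
  non-monotone relevance can be missed.
* Best-first search is a heuristic: on adversarial correlation structures
  it can return a local optimum (it matches exhaustive enumeration on
  data-derived correlation caches in the test suite).
* The 70% identity reduction is window-level; full-protein homology is out
  of scope.
* No probability recalibration, no ROC machinery beyond the four protocol
  metrics, and no alternative classifiers — the package deliberately stays
  with the logistic integration model.
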