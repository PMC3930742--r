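# acepred

Prediction of N<sup>ε</sup>-lysine acetylation sites from protein sequence.

Lysine acetylation is a reversible post-translational modification involved
in chromatin regulation, protein stability and disease. Experimental mapping
of acetylated lysines (mass spectrometry, ChIP, radiolabelling) is slow, so
sequence-based classifiers are used to triage candidate sites. `acepred`
implements such a classifier for bioinformaticians who have protein FASTA
files and (for training) lists of known acetylation sites.

## The model

Every lysine is represented by a peptide window of `2n + 1` residues centered
on it (terminal overruns padded with `X`). Three feature blocks are computed
per window:

* **AAPP** — for each AAindex physicochemical scale, the mean scale value of
  the window's residues, `(1/L) Σ_j p_j`, min–max normalized to `[0, 1]` on
  the training set. Scales are filtered by correlation-based feature-subset
  selection (CFS): best-first search over subsets scored by
  `Merit(S) = k r̄_cf / √(k + k(k−1) r̄_ff)`,
  which rewards class correlation and penalizes redundancy.
* **TPM** — a first-order Markov log-likelihood ratio over adjacent residues:
  `Σ_i ln( T⁺[x_i, x_{i+1}] / T⁻[x_i, x_{i+1}] )`, where `T⁺`/`T⁻` are
  row-stochastic transition matrices estimated (with Laplace pseudocount)
  from acetylated and non-acetylated training windows.
* **PSSC** — a position-specific composition score
  `Σ_j s[x_j, j]` with `s[i, j] = (f⁺_ij − f⁻_ij) · r_j`, the signed
  class-frequency difference weighted by the positional information content
  `r_j = log2(20) − H_j` (sequence-logo convention).

The three blocks are integrated by a logistic regression
`P(acetylated | x) = 1 / (1 + e^{−θ·(1, x)})` fitted by maximum likelihood
(Newton/IRLS with step-halving; optional small ridge for near-separable
data). Evaluation follows the field's protocol: peptide-level homology
reduction (>70% window identity collapsed), balanced negative resampling
iterated 10 times, stratified 10-fold cross-validation, and Sn / Sp / Acc /
MCC reporting, plus a window-size scan to choose `n`.

A synthetic-data module generates peptide windows and whole proteins with
the compositional structure reported for real acetylation data (K/R/G
enriched around positive sites, L/S/E around negatives), so the entire
pipeline is testable without any database download.

## Worked example

```r
library(acepred)

aa   <- parse_aaindex(aaindex_fixture_path())   # packaged AAindex subset
cfg  <- synthetic_config(n_per_class = 1000, seed = 42)
peps <- generate_peptides(cfg)                  # labeled 21-mer windows

model <- train_model(peps, aaindex = aa)
model
#> Acetylation-site prediction model
#>   window: 2n+1 = 21 (n = 10)
#>   feature blocks: aapp + tpm + pssc
#>   selected AAPP scales: SYNBAS0001, SYNACD0001
#>   threshold: 0.5

tidy(model)
#> # A tibble: 5 × 2
#>   term        estimate
#>   <chr>          <dbl>
#> 1 (Intercept)   0.0981
#> 2 SYNBAS0001   -5.31
#> 3 SYNACD0001    3.75
#> 4 tpm_score     0.464
#> 5 pssc_score   80.4
```

CFS kept two of the eight packaged scales; the large `pssc_score` weight
says positional composition is the dominant signal on these data. Scoring
every lysine of a new protein:

```r
new_prot <- tibble::tibble(id = "demo", sequence = "MSGRGKQGGKARAKAK...")
pred <- predict(model, extract_windows(new_prot, n = 10))
dplyr::select(pred, protein_id, center_pos, probability, predicted)
#> # A tibble: 5 × 4   (first rows)
#>   protein_id center_pos probability predicted
#> 1 demo                6       1.000         1
#> 2 demo               10       1.000         1
#> 3 demo               14       0.997         1
```

`probability` is the logistic likelihood of acetylation; `predicted` applies
the 0.5 threshold (ties positive). Cross-validated performance, with every
pipeline stage re-estimated inside each training fold:

```r
kfold_cv(peps, aaindex = aa, k = 10, seed = 7)
#> 10-fold stratified CV (features: aapp + tpm + pssc)
#> fold-averaged:  Sn 0.949  Sp 0.943  Acc 0.946  MCC 0.8928
#> pooled:         Sn 0.949  Sp 0.943  Acc 0.946  MCC 0.892
```

On this synthetic set (enrichment strength 0.3) the combined model reaches
~95% accuracy; `balanced_resampling_cv()` and `window_scan()` run the full
repeated-resampling protocol and the window-length scan, and
`autoplot()` methods visualize the scan, the per-iteration metrics and the
PSSC matrix. A command-line wrapper (`inst/cli/acepred`) exposes
`simulate`, `reduce`, `train`, `predict`, `cv` and `scan` subcommands; each
run writes a `config.txt` echo that reproduces it exactly.

## Notes

* The packaged AAindex file is a small format-faithful synthetic subset
  (plus the published Kyte–Doolittle hydropathy scale); point
  `parse_aaindex()` at a full AAindex1 release for real analyses.
* See the methods vignette (`vignettes/acepred-methods.Rmd`) for model
  assumptions, parameter defaults, and known limitations.
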