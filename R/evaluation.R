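#' Confusion counts at a decision threshold
#'
#' @param y_true Binary labels (0/1).
#' @param p Predicted probabilities (or scores), same length.
#' @param threshold Scores `>= threshold` are called positive
#'   (default 0.5).
#' @return A one-row tibble with columns `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, p, threshold = 0.5) {
  if (length(y_true) != length(p)) {
    abort("`y_true` and `p` must have the same length")
  }
  pred <- as.integer(p >= threshold)
  tibble::tibble(
    TP = sum(pred == 1L & y_true == 1L),
    FP = sum(pred == 1L & y_true == 0L),
    TN = sum(pred == 0L & y_true == 0L),
    FN = sum(pred == 0L & y_true == 1L)
  )
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' `Sn = TP / (TP + FN)`, `Sp = TN / (TN + FP)`,
#' `Acc = (TP + TN) / total`, and
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' Any metric whose denominator is zero is defined as 0.
#'
#' @param counts A one-row tibble (or list) with `TP`, `FP`, `TN`, `FN`.
#' @return A one-row tibble with columns `Sn`, `Sp`, `Acc`, `MCC`
#'   (proportions in `[0, 1]`, MCC in `[-1, 1]`).
#' @export
#' @examples
#' compute_metrics(tibble::tibble(TP = 68, FN = 32, TN = 70, FP = 30))
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); FP <- as.numeric(counts$FP)
  TN <- as.numeric(counts$TN); FN <- as.numeric(counts$FN)
  total <- TP + FP + TN + FN
  if (any(total == 0)) abort("no evaluated peptides: all counts are zero")
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  tibble::tibble(
    Sn = safe_div(TP, TP + FN),
    Sp = safe_div(TN, TN + FP),
    Acc = (TP + TN) / total,
    MCC = safe_div(TP * TN - FP * FN, mcc_den)
  )
}

# Stratified fold assignment: within each class, a seeded shuffle then
# round-robin fold labels, preserving class proportions per fold.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      abort(sprintf("class %s has fewer members (%d) than folds (%d)",
                    cls, length(idx), k))
    }
    set.seed(derive_seed(seed, 7L, cls))
    idx <- sample(idx)
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Splits the labeled peptides into `k` stratified folds; for each fold
#' the entire pipeline state — transition matrices, PSSC matrix,
#' normalization bounds and CFS selection — is re-estimated on the
#' training folds only, a logistic model is fitted, and the held-out
#' fold is scored.  Reported are per-fold metrics, their mean, and
#' pooled (micro-averaged) metrics from the summed confusion counts.
#'
#' @param peptides Labeled peptide tibble (both classes present).
#' @param aaindex AAindex tibble (required when `"aapp"` is in
#'   `features`).
#' @param k Number of folds, default 10.
#' @param seed Integer seed controlling the fold assignment.
#' @param features,... Passed to [train_model()].
#' @param threshold Decision threshold, default 0.5.
#' @return An object of class `cv_result`: list with `folds` (tibble of
#'   per-fold counts and metrics), `summary` (fold-averaged metrics),
#'   `pooled` (micro-averaged metrics) and the call configuration.
#'   `tidy()` returns the per-fold tibble, `glance()` the one-row
#'   summary.
#' @export
kfold_cv <- function(peptides, aaindex = NULL, k = 10L, seed = 1L,
                     features = c("aapp", "tpm", "pssc"),
                     threshold = 0.5, ...) {
  y <- peptides$label
  if (!all(y %in% c(0L, 1L))) abort("peptides must be labeled 0/1")
  fold <- stratified_folds(y, k, seed)
  per_fold <- purrr::map(seq_len(k), function(f) {
    train <- peptides[fold != f, , drop = FALSE]
    test <- peptides[fold == f, , drop = FALSE]
    model <- train_model(train, aaindex = aaindex, features = features,
                         threshold = threshold, ...)
    pred <- predict(model, test)
    cc <- confusion(test$label, pred$probability, threshold)
    dplyr::bind_cols(tibble::tibble(fold = f), cc, compute_metrics(cc))
  })
  folds <- dplyr::bind_rows(per_fold)
  pooled_counts <- dplyr::summarise(folds, TP = sum(.data$TP),
                                    FP = sum(.data$FP), TN = sum(.data$TN),
                                    FN = sum(.data$FN))
  structure(list(
    folds = folds,
    summary = dplyr::summarise(folds, Sn = mean(.data$Sn), Sp = mean(.data$Sp),
                               Acc = mean(.data$Acc), MCC = mean(.data$MCC)),
    pooled = compute_metrics(pooled_counts),
    pooled_counts = pooled_counts,
    k = k, seed = seed, features = features, threshold = threshold
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold stratified CV (features: %s)\n",
              x$k, paste(x$features, collapse = " + ")))
  cat("fold-averaged: ")
  print(round(as.data.frame(x$summary), 4))
  cat("pooled:        ")
  print(round(as.data.frame(x$pooled), 4))
  invisible(x)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(x$summary,
                   tibble::tibble(pooled_Acc = x$pooled$Acc,
                                  pooled_MCC = x$pooled$MCC,
                                  k = x$k, seed = x$seed))
}

#' Repeated balanced negative resampling around k-fold CV
#'
#' Emulates the study protocol for unbalanced data: in each iteration a
#' negative set of the same size as the positive set is drawn without
#' replacement from the negative pool, combined with all positives, and
#' evaluated by stratified k-fold CV.  Metrics are reported per
#' iteration with their mean and standard deviation; the headline is the
#' mean over iterations of the fold-averaged metrics.
#'
#' @param positives Tibble of positive peptides (`label` 1).
#' @param negatives_pool Tibble of candidate negatives (`label` 0), at
#'   least as many rows as `positives`.
#' @param iterations Number of resampling iterations, default 10.
#' @param k Folds per iteration, default 10.
#' @param seed Master seed; per-iteration seeds are derived
#'   deterministically so any iteration can be reproduced alone.
#' @param ... Passed to [kfold_cv()] / [train_model()].
#' @return An object of class `resampling_result`: list with
#'   `iterations` (per-iteration fold-averaged metrics tibble),
#'   `summary` (mean and sd), `cv` (list of `cv_result`s) and `draws`
#'   (the sampled negative set of each iteration, for audit).
#' @export
balanced_resampling_cv <- function(positives, negatives_pool,
                                   iterations = 10L, k = 10L, seed = 1L,
                                   ...) {
  stopifnot(iterations >= 1L)
  if (nrow(negatives_pool) < nrow(positives)) {
    abort("negative pool is smaller than the positive set")
  }
  fold_seed <- derive_seed(seed, 19L)
  runs <- purrr::map(seq_len(iterations), function(i) {
    set.seed(derive_seed(seed, 11L, i))
    # sorted draw: the sample is a set, so keep pool order for stability
    neg <- negatives_pool[sort(sample.int(nrow(negatives_pool),
                                          nrow(positives))), ,
                          drop = FALSE]
    # the fold seed is shared across iterations so that identical draws
    # (e.g. a pool no larger than the positive set) give identical results
    cv <- kfold_cv(dplyr::bind_rows(positives, neg), k = k, seed = fold_seed, ...)
    list(cv = cv, draw = neg,
         row = dplyr::bind_cols(tibble::tibble(iteration = i), cv$summary,
                                tibble::tibble(pooled_Acc = cv$pooled$Acc,
                                               pooled_MCC = cv$pooled$MCC)))
  })
  per_iter <- dplyr::bind_rows(purrr::map(runs, "row"))
  metric_cols <- c("Sn", "Sp", "Acc", "MCC", "pooled_Acc", "pooled_MCC")
  summary <- dplyr::bind_rows(
    dplyr::summarise(per_iter, dplyr::across(dplyr::all_of(metric_cols), mean)),
    dplyr::summarise(per_iter, dplyr::across(dplyr::all_of(metric_cols),
                                             stats::sd))
  )
  summary$statistic <- c("mean", "sd")
  structure(list(iterations = per_iter, summary = summary,
                 cv = purrr::map(runs, "cv"), draws = purrr::map(runs, "draw"),
                 seed = seed, k = k),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Balanced resampling: %d iterations of %d-fold CV\n",
              nrow(x$iterations), x$k))
  print(as.data.frame(dplyr::mutate(x$summary,
                                    dplyr::across(dplyr::where(is.numeric),
                                                  ~ round(.x, 4)))))
  invisible(x)
}

#' @method tidy resampling_result
#' @export
tidy.resampling_result <- function(x, ...) x$iterations

#' @method glance resampling_result
#' @export
glance.resampling_result <- function(x, ...) {
  m <- x$summary[x$summary$statistic == "mean", ]
  m$statistic <- NULL
  m
}

#' Window-size scan
#'
#' Re-extracts windows at each half-width `n`, builds a balanced
#' training set around the annotated positives (negatives drawn from the
#' remaining lysines by repeated balanced resampling), runs the CV
#' protocol, and tabulates the four metrics per window size — the
#' procedure used to pick the best peptide length.
#'
#' @param proteins Protein tibble (see [read_fasta()]).
#' @param sites Annotation tibble of positive sites (`protein_id`,
#'   `position`, `label` 1).
#' @param n_values Half-widths to scan, e.g. `6:12` for window sizes
#'   13-25.
#' @param aaindex AAindex tibble.
#' @param iterations Balanced-resampling iterations per window size,
#'   default 1 (raise to 10 for the full protocol).
#' @param k Folds, default 10.
#' @param seed Master seed.
#' @param ... Passed to [kfold_cv()] / [train_model()].
#' @return A tibble of class `window_scan` with one row per window size:
#'   `n`, `window_size`, `Sn`, `Sp`, `Acc`, `MCC` (fold- and
#'   iteration-averaged), plus `pooled_Acc`, `pooled_MCC`.
#' @export
window_scan <- function(proteins, sites, n_values, aaindex = NULL,
                        iterations = 1L, k = 10L, seed = 1L, ...) {
  stopifnot(length(n_values) >= 1L)
  rows <- purrr::map(sort(as.integer(n_values)), function(n) {
    all_windows <- extract_windows(proteins, n = n)
    key <- paste(all_windows$protein_id, all_windows$center_pos)
    pos_key <- paste(sites$protein_id, sites$position)
    labels <- ifelse(key %in% pos_key, 1L, 0L)
    windows <- dplyr::mutate(all_windows, label = labels)
    res <- balanced_resampling_cv(windows[windows$label == 1L, ],
                                  windows[windows$label == 0L, ],
                                  iterations = iterations, k = k,
                                  seed = derive_seed(seed, 13L, n),
                                  aaindex = aaindex, ...)
    m <- glance(res)
    dplyr::bind_cols(tibble::tibble(n = n, window_size = 2L * n + 1L), m)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("window_scan", class(out))
  out
}

#' Write a metrics table with percentages
#'
#' Writes a TSV in the layout of the published performance tables: a row
#' label followed by Sn, Sp, Acc and MCC as percentages.
#'
#' @param tab Tibble containing columns `Sn`, `Sp`, `Acc`, `MCC` (as
#'   proportions) and a label column.
#' @param path Output path.
#' @param label_col Name of the label column (default the first column).
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(tab, path, label_col = names(tab)[1]) {
  out <- tibble::tibble(
    label = tab[[label_col]],
    `Sn (%)` = round(100 * tab$Sn, 2),
    `Sp (%)` = round(100 * tab$Sp, 2),
    `Acc (%)` = round(100 * tab$Acc, 2),
    `MCC (%)` = round(100 * tab$MCC, 2)
  )
  names(out)[1] <- label_col
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
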