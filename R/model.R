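#' Train an acetylation-site prediction model
#'
#' Runs the full training pipeline on labeled peptide windows:
#' class-conditional transition matrices (TPM), position-specific symbol
#' composition matrix (PSSC), raw AAPP features with min-max
#' normalization fitted on the training set, optional CFS feature
#' selection over the AAPP block, and a logistic regression integrating
#' the selected AAPP features with the TPM and PSSC scores.  All
#' estimated state is frozen into the returned model so new peptides are
#' featurized identically.
#'
#' @param peptides Tibble of training peptides (columns `window`,
#'   `label` with both classes present; see [extract_windows()]).
#' @param aaindex AAindex tibble from [parse_aaindex()], or `NULL` when
#'   the AAPP block is not used.
#' @param features Character subset of `c("aapp", "tpm", "pssc")`;
#'   default all three.
#' @param cfs Run CFS selection on the AAPP block (default `TRUE`).  If
#'   selection returns the empty set the AAPP block is dropped.
#' @param tpm_pseudocount Laplace pseudocount for transition estimation
#'   (default 1).
#' @param pssc_pseudocount Per-cell pseudocount for positional
#'   frequencies (default 0.5).
#' @param pssc_mode `"difference"` (default) or `"logodds"` PSSC scoring.
#' @param l2,tol,max_iter Passed to [fit_logistic()].
#' @param stale_limit Passed to [best_first_search()].
#' @param threshold Decision threshold stored with the model, default 0.5.
#' @return An object of class `acep_model` holding the logistic weights
#'   and the frozen feature pipeline (selected scales, normalization
#'   bounds, both transition matrices, PSSC matrix, half-width `n`).
#' @export
train_model <- function(peptides, aaindex = NULL,
                        features = c("aapp", "tpm", "pssc"),
                        cfs = TRUE,
                        tpm_pseudocount = 1, pssc_pseudocount = 0.5,
                        pssc_mode = c("difference", "logodds"),
                        l2 = 1e-6, tol = 1e-8, max_iter = 100L,
                        stale_limit = 5L, threshold = 0.5) {
  pssc_mode <- match.arg(pssc_mode)
  features <- match.arg(features, c("aapp", "tpm", "pssc"),
                        several.ok = TRUE)
  if (!all(peptides$label %in% c(0L, 1L))) {
    abort("training peptides must be labeled 0/1")
  }
  y <- peptides$label
  if (length(unique(y)) < 2L) abort("both classes must be present")
  pos <- peptides[y == 1L, ]
  neg <- peptides[y == 0L, ]
  width <- unique(nchar(peptides$window))
  if (length(width) != 1L) abort("all training windows must share one length")
  n <- (width - 1L) %/% 2L

  state <- list(features = features, n = n, threshold = threshold,
                pssc_mode = pssc_mode, tpm_pseudocount = tpm_pseudocount,
                pssc_pseudocount = pssc_pseudocount)

  if ("aapp" %in% features) {
    if (is.null(aaindex) || nrow(aaindex) == 0L) {
      abort("`aaindex` is required when the AAPP feature block is enabled")
    }
    raw <- aapp_features(peptides, aaindex)
    bounds <- fit_normalization(raw)
    norm <- apply_normalization(raw, bounds)
    if (cfs && ncol(norm) > 1L) {
      cache <- correlation_cache(norm, y)
      sel <- best_first_search(cache, stale_limit = stale_limit)
      selected <- sel$names
    } else {
      selected <- colnames(norm)
    }
    if (length(selected) == 0L) {
      state$features <- setdiff(state$features, "aapp")
    } else {
      keep <- aaindex$accession %in% selected
      state$aaindex <- aaindex[keep, , drop = FALSE]
      state$bounds <- bounds[bounds$feature %in% selected, , drop = FALSE]
    }
  }
  if ("tpm" %in% features) {
    state$t_pos <- estimate_transitions(pos, pseudocount = tpm_pseudocount)
    state$t_neg <- estimate_transitions(neg, pseudocount = tpm_pseudocount)
  }
  if ("pssc" %in% features) {
    fp <- positional_frequencies(pos, pseudocount = pssc_pseudocount)
    fn <- positional_frequencies(neg, pseudocount = pssc_pseudocount)
    pooled <- positional_frequencies(peptides, pseudocount = pssc_pseudocount)
    r <- position_information(pooled)
    state$pssc <- build_pssc_matrix(fp, fn, r, mode = pssc_mode)
  }

  X <- featurize_state(peptides, state)
  fit <- fit_logistic(X, y, l2 = l2, tol = tol, max_iter = max_iter)
  structure(c(state, list(fit = fit, coef = fit$coef,
                          feature_names = colnames(X))),
            class = "acep_model")
}

# Assemble the feature matrix for a peptide set under a frozen pipeline
# state: [selected AAPP (normalized) ..., tpm_score, pssc_score].
featurize_state <- function(peptides, state) {
  width <- unique(nchar(peptides$window))
  if (length(width) > 1L || (length(width) == 1L && width != 2L * state$n + 1L)) {
    abort(sprintf("window length %s does not match the model's 2n+1 = %d",
                  paste(width, collapse = "/"), 2L * state$n + 1L))
  }
  blocks <- list()
  if ("aapp" %in% state$features) {
    raw <- aapp_features(peptides, state$aaindex)
    blocks$aapp <- apply_normalization(raw, state$bounds)
  }
  if ("tpm" %in% state$features) {
    blocks$tpm <- matrix(tpm_score(peptides, state$t_pos, state$t_neg),
                         ncol = 1L, dimnames = list(NULL, "tpm_score"))
  }
  if ("pssc" %in% state$features) {
    blocks$pssc <- matrix(pssc_score(peptides, state$pssc),
                          ncol = 1L, dimnames = list(NULL, "pssc_score"))
  }
  do.call(cbind, blocks)
}

#' Featurize peptides with a trained model's frozen pipeline
#'
#' @param peptides Tibble of peptides whose window length matches the
#'   model's.
#' @param model An `acep_model`.
#' @return A numeric feature matrix (selected AAPP columns, then
#'   `tpm_score`, then `pssc_score`).
#' @export
featurize <- function(peptides, model) {
  stopifnot(inherits(model, "acep_model"))
  featurize_state(peptides, model)
}

#' Predict acetylation probabilities for peptides
#'
#' @param object An `acep_model`.
#' @param peptides Tibble of peptides (window length must match).
#' @param ... Unused.
#' @return The peptide tibble with added columns `probability` and
#'   `predicted` (1 if `probability >= threshold`).
#' @export
predict.acep_model <- function(object, peptides, ...) {
  X <- featurize_state(peptides, object)
  p <- predict_prob(object$fit, X)
  dplyr::mutate(peptides, probability = p,
                predicted = as.integer(p >= object$threshold))
}

#' @export
print.acep_model <- function(x, ...) {
  cat("Acetylation-site prediction model\n")
  cat(sprintf("  window: 2n+1 = %d (n = %d)\n", 2 * x$n + 1, x$n))
  cat(sprintf("  feature blocks: %s\n", paste(x$features, collapse = " + ")))
  if (!is.null(x$aaindex)) {
    cat(sprintf("  selected AAPP scales: %s\n",
                paste(x$aaindex$accession, collapse = ", ")))
  }
  cat(sprintf("  threshold: %g\n", x$threshold))
  invisible(x)
}

#' @method tidy acep_model
#' @export
tidy.acep_model <- function(x, ...) tidy(x$fit)

#' @method glance acep_model
#' @export
glance.acep_model <- function(x, ...) {
  dplyr::mutate(glance(x$fit),
                n_features = length(x$feature_names),
                window_size = 2L * x$n + 1L)
}
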