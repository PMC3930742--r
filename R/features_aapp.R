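#' Mean physicochemical property of a peptide window (AAPP)
#'
#' The AAPP value of a window under one AAindex scale is the mean scale
#' value of its residues, `(1/L) * sum(p_j)`, where `L` counts only real
#' residues: pad symbols (`X`) contribute nothing to either the sum or
#' the length, so terminal windows are averaged over what is actually
#' there.
#'
#' @param windows Character vector of window strings.
#' @param values Named numeric vector over the 20 residues (one element
#'   of the `values` list-column from [parse_aaindex()]).
#' @return Numeric vector of per-window means.
#' @export
#' @examples
#' v <- setNames(seq_len(20), aa_alphabet())
#' aapp_value(c("AKA", "XKA"), v)
aapp_value <- function(windows, values) {
  codes <- window_code_matrix(windows)
  vals <- matrix(values[AA_ALPHABET][codes], nrow = nrow(codes))
  L <- rowSums(!is.na(codes))
  rowSums(vals, na.rm = TRUE) / L
}

#' Raw AAPP feature block for a set of peptides
#'
#' @param peptides Tibble with a `window` column.
#' @param aaindex Tibble from [parse_aaindex()].
#' @return A numeric matrix, one row per peptide, one column per scale
#'   (named by accession).
#' @export
aapp_features <- function(peptides, aaindex) {
  codes <- window_code_matrix(peptides$window)
  L <- rowSums(!is.na(codes))
  out <- vapply(aaindex$values, function(v) {
    vals <- matrix(v[AA_ALPHABET][codes], nrow = nrow(codes))
    rowSums(vals, na.rm = TRUE) / L
  }, numeric(nrow(codes)))
  if (nrow(peptides) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- aaindex$accession
  out
}

#' Fit min-max normalization bounds on training AAPP values
#'
#' Bounds are fitted on the training peptides only and later applied,
#' with clamping, to unseen peptides — validation data never informs the
#' normalization.
#'
#' @param features Numeric matrix from [aapp_features()] (training rows).
#' @return A tibble with columns `feature`, `min`, `max`.
#' @export
fit_normalization <- function(features) {
  if (NROW(features) < 1L) abort("at least one training peptide is required")
  tibble::tibble(
    feature = colnames(features),
    min = unname(apply(features, 2, min)),
    max = unname(apply(features, 2, max))
  )
}

#' Apply min-max normalization
#'
#' Maps each feature to `(value - min) / (max - min)`, clamped to
#' `[0, 1]` so that test values beyond the training range stay in bounds.
#' A degenerate (constant) feature maps to 0.5 everywhere, which makes it
#' carry no information — feature selection will discard it.
#'
#' @param features Numeric matrix (columns must match the fitted bounds).
#' @param bounds Tibble from [fit_normalization()].
#' @return A numeric matrix of the same shape with entries in `[0, 1]`.
#' @export
apply_normalization <- function(features, bounds) {
  features <- as.matrix(features)
  if (!identical(colnames(features), bounds$feature)) {
    features <- features[, bounds$feature, drop = FALSE]
  }
  rng <- bounds$max - bounds$min
  out <- sweep(features, 2, bounds$min, "-")
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0.5
  pmin(pmax(out, 0), 1)
}
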