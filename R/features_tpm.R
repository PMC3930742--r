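#' Estimate a first-order residue transition matrix (TPM)
#'
#' Counts adjacent residue pairs across the supplied windows and converts
#' them to row-stochastic transition probabilities with Laplace
#' smoothing: `P(b | a) = (n_ab + c) / (n_a. + 20 c)` with pseudocount
#' `c`.  Pairs that touch the pad symbol `X` are skipped, so terminal
#' padding never contributes phantom transitions.  A row with no observed
#' pairs (and zero pseudocount) falls back to the uniform distribution.
#'
#' @param peptides Tibble with a `window` column, or a character vector
#'   of windows.
#' @param pseudocount Laplace pseudocount, default 1 (guarantees strictly
#'   positive entries and finite log-ratios).
#' @return An object of class `transition_matrix`: a list with `probs`
#'   (20 x 20 row-stochastic matrix in [aa_alphabet()] order), `counts`
#'   (raw pair counts) and `pseudocount`.
#' @export
estimate_transitions <- function(peptides, pseudocount = 1) {
  windows <- if (is.character(peptides)) peptides else peptides$window
  stopifnot(length(windows) >= 1L, pseudocount >= 0)
  codes <- window_code_matrix(windows)
  L <- ncol(codes)
  if (L < 2L) abort("windows must have length >= 2 to contain a transition")
  a <- codes[, -L, drop = FALSE]
  b <- codes[, -1L, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  counts <- matrix(tabulate((a[ok] - 1L) * 20L + b[ok], nbins = 400L),
                   nrow = 20L, byrow = TRUE,
                   dimnames = list(AA_ALPHABET, AA_ALPHABET))
  denom <- rowSums(counts) + 20 * pseudocount
  probs <- (counts + pseudocount) / denom
  probs[denom == 0, ] <- 1 / 20
  structure(list(probs = probs, counts = counts, pseudocount = pseudocount),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("First-order residue transition matrix (pseudocount",
      x$pseudocount, ")\n")
  print(round(x$probs[1:5, 1:5], 3))
  cat("... 20 x 20, rows sum to 1\n")
  invisible(x)
}

#' Markov log-likelihood-ratio score of peptide windows (TPM feature)
#'
#' For each window, sums `ln(T_pos[a, b] / T_neg[a, b])` over its
#' adjacent residue pairs, where the two matrices are the
#' class-conditional transition matrices of acetylated and non-acetylated
#' training peptides.  Pairs touching the pad symbol are skipped; a
#' window with no valid pair scores 0.  Higher scores indicate the
#' acetylated class.
#'
#' @param peptides Tibble with a `window` column, or character vector.
#' @param t_pos,t_neg `transition_matrix` objects for the positive and
#'   negative class.
#' @return Numeric vector of log-likelihood-ratio scores (natural log).
#' @export
tpm_score <- function(peptides, t_pos, t_neg) {
  windows <- if (is.character(peptides)) peptides else peptides$window
  if (any(t_pos$probs <= 0) || any(t_neg$probs <= 0)) {
    abort("transition matrices must have strictly positive entries; use pseudocount > 0")
  }
  codes <- window_code_matrix(windows)
  L <- ncol(codes)
  if (L < 2L) return(rep(0, length(windows)))
  lr <- log(t_pos$probs) - log(t_neg$probs)
  a <- codes[, -L, drop = FALSE]
  b <- codes[, -1L, drop = FALSE]
  contrib <- matrix(0, nrow = nrow(codes), ncol = L - 1L)
  ok <- !is.na(a) & !is.na(b)
  contrib[ok] <- lr[cbind(a[ok], b[ok])]
  rowSums(contrib)
}

#' Write / read a transition matrix as TSV
#'
#' 21 columns: the row residue followed by the 20 target residues.  The
#' round trip is exact (full double precision).
#'
#' @param tm A `transition_matrix`.
#' @param path File path.
#' @return `path` (writer) or a `transition_matrix` (reader).
#' @export
write_transition_matrix <- function(tm, path) {
  df <- data.frame(residue = rownames(tm$probs),
                   format(tm$probs, digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transition_matrix
#' @export
read_transition_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  probs <- as.matrix(df[, -1])
  rownames(probs) <- df[[1]]
  structure(list(probs = probs, counts = NULL, pseudocount = NA_real_),
            class = "transition_matrix")
}
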