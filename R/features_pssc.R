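#' Positional residue frequencies of a peptide set
#'
#' Relative frequency of each residue at each window position, with a
#' per-cell pseudocount: `(n_ij + c) / (N_j + 20 c)` where `N_j` counts
#' the non-pad residues at position `j`.  Pads are excluded from both
#' numerator and denominator, so terminal padding does not dilute the
#' composition.
#'
#' @param peptides Tibble with a `window` column, or character vector of
#'   equal-length windows.
#' @param pseudocount Per-residue pseudocount, default 0.5.
#' @return A 20 x (window length) matrix of class `positional_freq`;
#'   rows in [aa_alphabet()] order, columns are window positions.  Each
#'   column sums to 1.
#' @export
positional_frequencies <- function(peptides, pseudocount = 0.5) {
  windows <- if (is.character(peptides)) peptides else peptides$window
  if (length(windows) == 0L) abort("at least one peptide is required")
  stopifnot(pseudocount >= 0)
  codes <- window_code_matrix(windows)
  counts <- apply(codes, 2, function(col) tabulate(col, nbins = 20L))
  denom <- colSums(counts) + 20 * pseudocount
  freq <- sweep(counts + pseudocount, 2, denom, "/")
  freq[, denom == 0] <- 1 / 20        # all-pad column, degenerate
  rownames(freq) <- AA_ALPHABET
  colnames(freq) <- window_position_labels(ncol(freq))
  structure(freq, class = c("positional_freq", "matrix"))
}

# Position labels -n ... 0 ... +n as used in sequence-logo displays.
window_position_labels <- function(width) {
  n <- (width - 1L) %/% 2L
  as.character(seq.int(-n, width - n - 1L))
}

#' Positional information content in bits
#'
#' `r_j = log2(20) - H_j`, where `H_j` is the Shannon entropy of the
#' residue distribution at position `j` (with `0 log 0 := 0`).  A fully
#' conserved position scores `log2(20) ~ 4.32` bits; a uniform position
#' scores 0.
#'
#' @param freq A `positional_freq` matrix, normally estimated from the
#'   pooled (positive + negative) training peptides.
#' @return Numeric vector of per-position information content, in bits.
#' @export
position_information <- function(freq) {
  h <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  log2(20) - h
}

#' Build the position-specific symbol composition (PSSC) score matrix
#'
#' Scores each (residue, position) cell by how much the residue is
#' enriched in acetylated over non-acetylated peptides at that position,
#' weighted by how informative the position is:
#' `s_ij = (f_pos_ij - f_neg_ij) * r_j` (the sequence-logo convention).
#' An alternative log-odds form
#' `s_ij = log2(f_pos_ij / f_neg_ij) * r_j` is available via `mode`.
#' Positive entries mark residues typical of acetylated peptides;
#' pad positions always score 0.
#'
#' @param freq_pos,freq_neg `positional_freq` matrices for the two
#'   classes (same dimensions).
#' @param r Information-content vector from [position_information()],
#'   normally computed on the pooled frequencies.
#' @param mode `"difference"` (default) or `"logodds"`.
#' @return A matrix of class `pssc_matrix` with the same shape as the
#'   inputs, plus attribute `r`.
#' @export
build_pssc_matrix <- function(freq_pos, freq_neg, r,
                              mode = c("difference", "logodds")) {
  mode <- match.arg(mode)
  if (!all(dim(freq_pos) == dim(freq_neg)) || length(r) != ncol(freq_pos)) {
    abort("dimension mismatch between class frequencies and information vector")
  }
  s <- switch(mode,
    difference = sweep(unclass(freq_pos) - unclass(freq_neg), 2, r, "*"),
    logodds = sweep(log2(unclass(freq_pos) / unclass(freq_neg)), 2, r, "*")
  )
  structure(s, class = c("pssc_matrix", "matrix"), r = r, mode = mode)
}

#' PSSC score of peptide windows
#'
#' Sums the matrix entries of the window's own residues along its
#' positions, `sum_j s[x_j, j]`; pad positions contribute 0.  A positive
#' total marks the window as leaning acetylated.
#'
#' @param peptides Tibble with a `window` column, or character vector.
#' @param m A `pssc_matrix` whose width matches the window length.
#' @return Numeric vector of scores.
#' @export
pssc_score <- function(peptides, m) {
  windows <- if (is.character(peptides)) peptides else peptides$window
  codes <- window_code_matrix(windows)
  if (ncol(codes) != ncol(m)) {
    abort(sprintf("window length %d does not match PSSC matrix width %d",
                  ncol(codes), ncol(m)))
  }
  s <- unclass(m)
  pos <- matrix(rep(seq_len(ncol(codes)), each = nrow(codes)),
                nrow = nrow(codes))
  contrib <- matrix(0, nrow = nrow(codes), ncol = ncol(codes))
  ok <- !is.na(codes)
  contrib[ok] <- s[cbind(codes[ok], pos[ok])]
  rowSums(contrib)
}

#' Write a PSSC matrix as TSV
#'
#' Rows are residues, columns the window positions labelled `-n ... +n`.
#'
#' @param m A `pssc_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_pssc_matrix <- function(m, path) {
  df <- data.frame(residue = rownames(m),
                   format(unclass(m), digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
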