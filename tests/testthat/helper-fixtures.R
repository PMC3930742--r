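# Shared fixtures built in code at test time.

fixture_aaindex <- function() parse_aaindex(aaindex_fixture_path())

# Peptide tibble from bare window strings.
make_peptides <- function(windows, label = NA_integer_) {
  width <- unique(nchar(windows))
  stopifnot(length(width) == 1)
  tibble::tibble(
    protein_id = sprintf("pep%03d", seq_along(windows)),
    center_pos = (width - 1L) %/% 2L + 1L,
    window = windows,
    n = (width - 1L) %/% 2L,
    label = rep(as.integer(label), length.out = length(windows))
  )
}

# Random row-stochastic 20x20 transition matrix.
random_transition_matrix <- function(seed, lo = 0.2, hi = 1) {
  set.seed(seed)
  P <- matrix(runif(400, lo, hi), 20, 20)
  P <- P / rowSums(P)
  dimnames(P) <- list(aa_alphabet(), aa_alphabet())
  structure(list(probs = P, counts = NULL, pseudocount = 0),
            class = "transition_matrix")
}

# Uniform transition matrix (all entries 1/20).
uniform_transition_matrix <- function() {
  P <- matrix(1 / 20, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  structure(list(probs = P, counts = NULL, pseudocount = 0),
            class = "transition_matrix")
}

write_temp_fasta <- function(ids, seqs) {
  path <- withr::local_tempfile(fileext = ".fasta",
                                .local_envir = parent.frame())
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# Exhaustive CFS optimum by subset enumeration (independent oracle).
exhaustive_cfs_best <- function(cache) {
  d <- length(cache$r_cf)
  best <- 0
  for (k in seq_len(d)) {
    combs <- utils::combn(d, k)
    for (j in seq_len(ncol(combs))) {
      best <- max(best, cfs_merit(combs[, j], cache))
    }
  }
  best
}
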