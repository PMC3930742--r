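#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and any letter outside the 20-residue
#' amino-acid alphabet (B, J, O, U, Z, `*`, ...) is mapped to the unknown
#' symbol `X`, so every downstream function sees a 21-symbol alphabet.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (first whitespace-delimited header
#'   token) and `sequence`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKAA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) {
    abort("empty FASTA input: no sequences found")
  }
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate sequence id(s) in FASTA: ",
                 paste(dup, collapse = ", ")))
  }
  seqs <- sanitize_sequence(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    abort("empty sequence in FASTA input")
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Read a site annotation table
#'
#' Tab-separated with three columns: protein id, 1-based lysine position,
#' label (1 = acetylated, 0 = not).
#'
#' @param path Path to the TSV file (no header).
#' @return A tibble with columns `protein_id`, `position`, `label`.
#' @export
read_sites <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("protein_id", "position", "label"),
                          colClasses = c("character", "integer", "integer"))
  tibble::as_tibble(df)
}

#' Write a site annotation table
#'
#' @param sites Tibble with columns `protein_id`, `position`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites[, c("protein_id", "position", "label")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract lysine-centered peptide windows
#'
#' For each candidate site a window of `2n + 1` residues centered on the
#' lysine is cut out of the protein; positions that fall outside the
#' sequence are padded with `X`.  Lysines close to a terminus are kept
#' (padded), not discarded.
#'
#' @param proteins Tibble with columns `id`, `sequence`
#'   (as from [read_fasta()]), or a single `ProteinRecord`-like row.
#' @param n Half-width of the window; the window length is `2n + 1`.
#' @param sites Optional tibble with columns `protein_id`, `position` and
#'   (optionally) `label` restricting extraction to annotated sites.  Every
#'   annotated position must hold a `K`.  When absent, one window per
#'   lysine is extracted with label `NA` (unknown).
#' @return A tibble of peptides with columns `protein_id`, `center_pos`
#'   (1-based position of the central K), `window`, `n`, `label`
#'   (integer 1/0/NA).
#' @export
#' @examples
#' p <- tibble::tibble(id = "p1", sequence = "MKAA")
#' extract_windows(p, n = 2)
extract_windows <- function(proteins, n, sites = NULL) {
  stopifnot(is.numeric(n), n >= 1)
  n <- as.integer(n)
  if (!all(c("id", "sequence") %in% names(proteins))) {
    abort("`proteins` must have columns `id` and `sequence`")
  }

  one_protein <- function(id, sequence, positions, labels) {
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    if (is.null(positions)) {
      positions <- which(chars == "K")
      labels <- rep(NA_integer_, length(positions))
    } else {
      bad <- positions[chars[positions] != "K"]
      if (length(bad) > 0L) {
        abort(sprintf(
          "annotation mismatch: position %d of protein '%s' is '%s', not 'K'",
          bad[1], id, chars[bad[1]]))
      }
    }
    if (length(positions) == 0L) {
      return(NULL)
    }
    padded <- c(rep(PAD_SYMBOL, n), chars, rep(PAD_SYMBOL, n))
    windows <- vapply(positions, function(p) {
      paste(padded[p:(p + 2L * n)], collapse = "")
    }, character(1))
    tibble::tibble(protein_id = id, center_pos = as.integer(positions),
                   window = windows, n = n, label = as.integer(labels))
  }

  if (is.null(sites)) {
    out <- purrr::pmap(list(proteins$id, proteins$sequence),
                       function(id, sequence) one_protein(id, sequence, NULL, NULL))
  } else {
    if (!all(c("protein_id", "position") %in% names(sites))) {
      abort("`sites` must have columns `protein_id` and `position`")
    }
    if (!"label" %in% names(sites)) {
      sites$label <- NA_integer_
    }
    split_sites <- split(sites, sites$protein_id)
    out <- purrr::pmap(list(proteins$id, proteins$sequence),
      function(id, sequence) {
        s <- split_sites[[id]]
        if (is.null(s)) return(NULL)
        one_protein(id, sequence, as.integer(s$position), as.integer(s$label))
      })
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(protein_id = character(), center_pos = integer(),
                          window = character(), n = integer(),
                          label = integer())
  }
  res
}

#' Write a prediction report
#'
#' Tab-separated rows of protein id, site position, window, predicted
#' acetylation probability and the thresholded call.  Probabilities at or
#' above the threshold are called positive.
#'
#' @param peptides Tibble of peptides (columns `protein_id`, `center_pos`,
#'   `window`).
#' @param probabilities Numeric vector in `[0, 1]`, one per peptide.
#' @param path Output path (or connection).
#' @param threshold Decision threshold, default 0.5; ties go positive.
#' @return The prediction tibble, invisibly.
#' @export
write_predictions <- function(peptides, probabilities, path, threshold = 0.5) {
  if (nrow(peptides) != length(probabilities)) {
    abort("`peptides` and `probabilities` must have the same length")
  }
  out <- tibble::tibble(
    protein_id = peptides$protein_id,
    position = peptides$center_pos,
    window = peptides$window,
    probability = probabilities,
    prediction = ifelse(probabilities >= threshold, "positive", "negative")
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(out)
}
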