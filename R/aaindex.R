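#' Parse an AAindex1 flat file
#'
#' Reads physicochemical amino-acid scales from the AAindex1 flat-file
#' format: records separated by `//`, with `H` (accession) and `D`
#' (description) lines, and an `I` line followed by two rows of ten
#' numbers in the canonical residue order
#' `A R N D C Q E G H I` / `L K M F P S T W Y V`.
#' Literal `NA` tokens are replaced by 0 so every scale is fully numeric.
#'
#' @param path Path to an AAindex1-format file.
#' @return A tibble with columns `accession`, `description` and `values`
#'   (a list-column of named numeric vectors over the 20 residues).
#' @seealso [aaindex_matrix()]
#' @export
parse_aaindex <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) {
    return(tibble::tibble(accession = character(),
                          description = character(),
                          values = list()))
  }
  recs <- split(lines, cumsum(c(0, head(grepl("^//", lines), -1))))
  out <- purrr::map(recs, parse_aaindex_record)
  out <- purrr::compact(out)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    res <- tibble::tibble(accession = character(), description = character(),
                          values = list())
  }
  res
}

parse_aaindex_record <- function(rec) {
  h <- grep("^H ", rec, value = TRUE)
  if (length(h) == 0L) return(NULL)           # trailing blank block
  accession <- trimws(sub("^H ", "", h[1]))
  d <- grep("^D ", rec, value = TRUE)
  description <- if (length(d) > 0) trimws(sub("^D ", "", d[1])) else ""
  i_at <- grep("^I ", rec)
  if (length(i_at) == 0L || i_at[1] + 2L > length(rec)) {
    abort(sprintf("malformed AAindex record '%s': missing I block", accession))
  }
  value_lines <- rec[(i_at[1] + 1L):(i_at[1] + 2L)]
  tokens <- unlist(strsplit(trimws(value_lines), "\\s+"))
  tokens <- tokens[tokens != ""]
  if (length(tokens) != 20L) {
    abort(sprintf("malformed AAindex record '%s': expected 20 values, got %d",
                  accession, length(tokens)))
  }
  vals <- suppressWarnings(as.numeric(tokens))
  vals[tokens == "NA"] <- 0          # the stated NA -> 0 substitution
  if (anyNA(vals)) {
    abort(sprintf("malformed AAindex record '%s': non-numeric value", accession))
  }
  tibble::tibble(accession = accession, description = description,
                 values = list(setNames(vals, AA_ALPHABET)))
}

#' AAindex scales as a residue-by-scale matrix
#'
#' @param aaindex Tibble from [parse_aaindex()].
#' @return A 20-row numeric matrix (rows = residues in [aa_alphabet()]
#'   order, columns = accessions).
#' @export
aaindex_matrix <- function(aaindex) {
  m <- do.call(cbind, aaindex$values)
  colnames(m) <- aaindex$accession
  rownames(m) <- AA_ALPHABET
  m
}

#' Path to the packaged synthetic AAindex fixture
#'
#' A small AAindex1-format file shipped for examples and tests.  It
#' contains the widely published Kyte-Doolittle hydropathy scale plus a
#' set of synthetic scales constructed for this package (accessions
#' `SYN...`), including one with `NA` entries to exercise the NA-to-0
#' rule.  It is a format-faithful stand-in for the full 541-scale AAindex
#' release, which users can supply themselves.
#'
#' @return A file path.
#' @export
aaindex_fixture_path <- function() {
  system.file("extdata", "aaindex_synthetic_subset.txt",
              package = "acepred", mustWork = TRUE)
}
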