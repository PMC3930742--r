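# Canonical residue alphabet, in AAindex row order (A R N D C Q E G H I /
# L K M F P S T W Y V).  'X' is the pad / unknown symbol and is never part
# of the modelled alphabet: every feature treats it as inert.

AA_ALPHABET <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

PAD_SYMBOL <- "X"

#' The 20-residue alphabet used throughout the package
#'
#' Returns the amino-acid single-letter codes in the order used for all
#' matrices (transition matrices, positional frequencies, PSSC scores):
#' the AAindex flat-file row order.
#'
#' @return A character vector of length 20.
#' @export
#' @examples
#' aa_alphabet()
aa_alphabet <- function() AA_ALPHABET

# Split equal-length window strings into a character matrix
# (one row per window, one column per position).
window_char_matrix <- function(windows) {
  stopifnot(is.character(windows))
  if (length(windows) == 0L) {
    return(matrix(character(), nrow = 0L, ncol = 0L))
  }
  lens <- unique(nchar(windows))
  if (length(lens) != 1L) {
    abort("all windows must have the same length")
  }
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = lens, byrow = TRUE)
}

# Integer-code matrix: residues mapped to 1..20 in alphabet order,
# pad symbol 'X' (and anything else) to NA.
window_code_matrix <- function(windows) {
  chars <- window_char_matrix(windows)
  codes <- match(chars, AA_ALPHABET)
  dim(codes) <- dim(chars)
  codes
}

# Map any non-standard residue letter (B J O U Z *, lower case already
# folded) to the pad/unknown symbol so downstream code sees a 21-symbol
# alphabet.
sanitize_sequence <- function(x) {
  x <- toupper(x)
  pattern <- sprintf("[^%s]", paste(AA_ALPHABET, collapse = ""))
  gsub(pattern, PAD_SYMBOL, x)
}

# Deterministic sub-seed derivation so any fold / iteration can be re-run
# in isolation.  Kept strictly below 2^31 - 1.
derive_seed <- function(master, ...) {
  offsets <- c(...)
  s <- as.double(master) %% 2147483647
  for (o in offsets) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s)
}
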