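# Plain-text model archive: self-describing sections, full double
# precision (hex floats), so a reloaded model predicts bit-identically.

fmt_num <- function(x) sprintf("%a", x)
parse_num <- function(x) as.numeric(x)

#' Save / load a trained model as a plain-text archive
#'
#' The archive is a single human-readable file with sections for the
#' logistic weights, the selected AAindex scales, the normalization
#' bounds, both transition matrices and the PSSC matrix.  Numbers are
#' stored as hexadecimal floating point, so `read_model(write_model(m))`
#' reproduces predictions bit-for-bit.
#'
#' @param model An `acep_model`.
#' @param path File path.
#' @return `path` (writer); an `acep_model` (reader).
#' @export
write_model <- function(model, path) {
  out <- c(
    "# acepred model archive v1",
    paste0("n\t", model$n),
    paste0("threshold\t", fmt_num(model$threshold)),
    paste0("features\t", paste(model$features, collapse = ",")),
    paste0("pssc_mode\t", model$pssc_mode),
    paste0("tpm_pseudocount\t", fmt_num(model$tpm_pseudocount)),
    paste0("pssc_pseudocount\t", fmt_num(model$pssc_pseudocount)),
    "[weights]",
    paste0(names(model$coef), "\t", fmt_num(model$coef))
  )
  if (!is.null(model$aaindex)) {
    out <- c(out, "[aaindex]",
             vapply(seq_len(nrow(model$aaindex)), function(i) {
               paste(c(model$aaindex$accession[i],
                       model$aaindex$description[i],
                       fmt_num(model$aaindex$values[[i]])),
                     collapse = "\t")
             }, character(1)),
             "[bounds]",
             paste0(model$bounds$feature, "\t", fmt_num(model$bounds$min),
                    "\t", fmt_num(model$bounds$max)))
  }
  if (!is.null(model$t_pos)) {
    out <- c(out, "[tpm_pos]", serialize_matrix(model$t_pos$probs),
             "[tpm_neg]", serialize_matrix(model$t_neg$probs))
  }
  if (!is.null(model$pssc)) {
    out <- c(out, "[pssc]", serialize_matrix(unclass(model$pssc)),
             "[pssc_r]", paste(fmt_num(attr(model$pssc, "r")), collapse = "\t"))
  }
  writeLines(out, path)
  invisible(path)
}

serialize_matrix <- function(m) {
  vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t")
  }, character(1))
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  sec_at <- grep("^\\[", lines)
  header <- lines[seq_len(sec_at[1] - 1L)]
  kv <- strsplit(header, "\t", fixed = TRUE)
  meta <- setNames(lapply(kv, function(x) paste(x[-1], collapse = "\t")),
                   vapply(kv, `[[`, character(1), 1))

  sections <- list()
  bounds_sec <- c(sec_at, length(lines) + 1L)
  for (i in seq_along(sec_at)) {
    nm <- gsub("^\\[|\\]$", "", lines[sec_at[i]])
    body <- lines[seq(sec_at[i] + 1L, bounds_sec[i + 1L] - 1L)]
    body <- body[nzchar(body)]
    sections[[nm]] <- body
  }

  split_rows <- function(body) strsplit(body, "\t", fixed = TRUE)
  read_matrix <- function(body, ncol_names) {
    rows <- split_rows(body)
    m <- t(vapply(rows, function(r) parse_num(r[-1]), numeric(length(rows[[1]]) - 1L)))
    rownames(m) <- vapply(rows, `[[`, character(1), 1)
    colnames(m) <- ncol_names
    m
  }

  w_rows <- split_rows(sections$weights)
  coef <- setNames(parse_num(vapply(w_rows, `[[`, character(1), 2)),
                   vapply(w_rows, `[[`, character(1), 1))

  state <- list(
    n = as.integer(meta$n),
    threshold = parse_num(meta$threshold),
    features = strsplit(meta$features, ",", fixed = TRUE)[[1]],
    pssc_mode = meta$pssc_mode,
    tpm_pseudocount = parse_num(meta$tpm_pseudocount),
    pssc_pseudocount = parse_num(meta$pssc_pseudocount),
    coef = coef,
    fit = structure(list(coef = coef, converged = NA), class = "logit_fit")
  )
  if (!is.null(sections$aaindex)) {
    rows <- split_rows(sections$aaindex)
    state$aaindex <- tibble::tibble(
      accession = vapply(rows, `[[`, character(1), 1),
      description = vapply(rows, `[[`, character(1), 2),
      values = lapply(rows, function(r) setNames(parse_num(r[-(1:2)]), AA_ALPHABET))
    )
    b_rows <- split_rows(sections$bounds)
    state$bounds <- tibble::tibble(
      feature = vapply(b_rows, `[[`, character(1), 1),
      min = parse_num(vapply(b_rows, `[[`, character(1), 2)),
      max = parse_num(vapply(b_rows, `[[`, character(1), 3))
    )
  }
  if (!is.null(sections$tpm_pos)) {
    state$t_pos <- structure(
      list(probs = read_matrix(sections$tpm_pos, AA_ALPHABET),
           counts = NULL, pseudocount = state$tpm_pseudocount),
      class = "transition_matrix")
    state$t_neg <- structure(
      list(probs = read_matrix(sections$tpm_neg, AA_ALPHABET),
           counts = NULL, pseudocount = state$tpm_pseudocount),
      class = "transition_matrix")
  }
  if (!is.null(sections$pssc)) {
    width <- 2L * state$n + 1L
    m <- read_matrix(sections$pssc, window_position_labels(width))
    r <- parse_num(strsplit(sections$pssc_r, "\t", fixed = TRUE)[[1]])
    state$pssc <- structure(m, class = c("pssc_matrix", "matrix"),
                            r = r, mode = state$pssc_mode)
  }
  state$feature_names <- c(
    if ("aapp" %in% state$features) state$aaindex$accession,
    if ("tpm" %in% state$features) "tpm_score",
    if ("pssc" %in% state$features) "pssc_score")
  structure(state, class = "acep_model")
}
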