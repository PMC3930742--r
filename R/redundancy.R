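#' Ungapped identity between two equal-length peptide windows
#'
#' Fraction of positions at which the two windows carry the same symbol.
#' The pad symbol `X` matches only `X`.  Vectorized over pairs.
#'
#' @param a,b Character vectors of equal-length window strings.
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
#' @examples
#' pairwise_identity("ABCDE", "ABCDF")
pairwise_identity <- function(a, b) {
  if (any(nchar(a) != nchar(b))) {
    abort("windows must have equal length for identity comparison")
  }
  ma <- window_char_matrix(a)
  mb <- window_char_matrix(b)
  if (length(a) == 1L && length(b) > 1L) ma <- ma[rep(1L, length(b)), , drop = FALSE]
  if (length(b) == 1L && length(a) > 1L) mb <- mb[rep(1L, length(a)), , drop = FALSE]
  rowMeans(ma == mb)
}

#' Homology reduction of peptide windows by greedy identity clustering
#'
#' Emulates a CD-HIT-style reduction on fixed-length windows: peptides are
#' scanned in a deterministic order and each one joins the first existing
#' cluster whose representative it matches at strictly more than
#' `threshold` identity, otherwise it founds a new cluster.  Only
#' representatives (the founding member of each cluster) are kept.
#' Positive and negative peptides are clustered separately so that
#' reduction never merges across labels; unknown-label peptides form a
#' third stratum.
#'
#' Because the windows all have one fixed length, "similarity" is
#' operationalized as ungapped positional identity — no alignment and no
#' short-word heuristics are involved, so the reduction is exact.
#'
#' @param peptides Tibble of peptides with columns `window` and `label`
#'   (as from [extract_windows()]).
#' @param threshold Identity above which two windows are considered
#'   redundant; default 0.7.
#' @param order `"input"` (default) processes peptides in input order;
#'   `"lexicographic"` sorts windows first for an order-independent result.
#' @return A tibble of representative peptides, in cluster-creation order.
#'   The full assignment is attached as attribute `"clusters"`: a tibble
#'   with the input rows plus `cluster` (integer id) and `representative`
#'   (logical) columns.  Retrieve it with `attr(x, "clusters")`.
#' @export
reduce_redundancy <- function(peptides, threshold = 0.7,
                              order = c("input", "lexicographic")) {
  order <- match.arg(order)
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(peptides) == 0L) {
    out <- peptides
    attr(out, "clusters") <- dplyr::mutate(peptides, cluster = integer(),
                                           representative = logical())
    return(out)
  }
  if (!"label" %in% names(peptides)) peptides$label <- NA_integer_

  idx <- seq_len(nrow(peptides))
  if (order == "lexicographic") idx <- idx[base::order(peptides$window[idx])]
  strata <- split(idx, factor(ifelse(is.na(peptides$label[idx]), "u",
                                     peptides$label[idx])))
  # keep stratum scan order deterministic: positives, negatives, unknown
  strata <- strata[order(match(names(strata), c("1", "0", "u")))]

  cluster_id <- integer(nrow(peptides))
  rep_rows <- integer(0)
  next_cluster <- 0L
  for (stratum in strata) {
    chars <- window_char_matrix(peptides$window[stratum])
    reps_local <- integer(0)     # row indices (within stratum) of representatives
    for (i in seq_along(stratum)) {
      assigned <- FALSE
      if (length(reps_local) > 0L) {
        rep_chars <- chars[reps_local, , drop = FALSE]
        ident <- rowMeans(rep_chars ==
                            matrix(chars[i, ], nrow = length(reps_local),
                                   ncol = ncol(chars), byrow = TRUE))
        hit <- which(ident > threshold)
        if (length(hit) > 0L) {
          cluster_id[stratum[i]] <- cluster_id[stratum[reps_local[hit[1]]]]
          assigned <- TRUE
        }
      }
      if (!assigned) {
        next_cluster <- next_cluster + 1L
        cluster_id[stratum[i]] <- next_cluster
        reps_local <- c(reps_local, i)
        rep_rows <- c(rep_rows, stratum[i])
      }
    }
  }

  clusters <- peptides
  clusters$cluster <- cluster_id
  clusters$representative <- seq_len(nrow(peptides)) %in% rep_rows
  reps <- peptides[rep_rows[base::order(cluster_id[rep_rows])], , drop = FALSE]
  attr(reps, "clusters") <- clusters
  reps
}

#' Write a cluster report
#'
#' One row per cluster: representative window, member count, member ids.
#'
#' @param reduced Result of [reduce_redundancy()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(reduced, path) {
  clusters <- attr(reduced, "clusters")
  if (is.null(clusters)) abort("`reduced` carries no cluster assignment")
  rep_tab <- clusters[clusters$representative, c("cluster", "window")]
  counts <- table(clusters$cluster)
  members <- vapply(split(paste0(clusters$protein_id, ":", clusters$center_pos),
                          clusters$cluster),
                    paste, character(1), collapse = ",")
  out <- tibble::tibble(
    representative = rep_tab$window[order(rep_tab$cluster)],
    member_count = as.integer(counts[as.character(sort(unique(clusters$cluster)))]),
    members = members[as.character(sort(unique(clusters$cluster)))]
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
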