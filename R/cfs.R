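#' Absolute Pearson correlation
#'
#' `|cor(x, y)|`, with the convention that a constant vector correlates 0
#' with anything (rather than propagating `NA`).  With a 0/1 class vector
#' this is the point-biserial correlation used for the feature-class
#' term of the CFS merit.
#'
#' @param x,y Numeric vectors of equal length (at least 2).
#' @return A number in `[0, 1]`.
#' @export
abs_pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    abort("`x` and `y` must have equal length >= 2")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  abs(cor(x, y))
}

#' Precompute the CFS correlation cache
#'
#' Feature-class correlations `r_cf` and pairwise feature-feature
#' correlations `r_ff` (both as absolute Pearson values, constants
#' correlating 0) for a feature matrix and a binary class vector.
#'
#' @param X Numeric matrix (rows = samples, columns = features).
#' @param y Binary class vector (0/1), length `nrow(X)`.
#' @return A list of class `cfs_cache` with `r_cf` (named vector) and
#'   `r_ff` (symmetric matrix, unit diagonal).
#' @export
correlation_cache <- function(X, y) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2L)
  r_cf <- abs(suppressWarnings(cor(X, y)))[, 1]
  r_cf[is.na(r_cf)] <- 0
  r_ff <- abs(suppressWarnings(cor(X)))
  r_ff[is.na(r_ff)] <- 0
  diag(r_ff) <- 1
  names(r_cf) <- colnames(X)
  structure(list(r_cf = r_cf, r_ff = r_ff), class = "cfs_cache")
}

#' CFS merit of a feature subset
#'
#' The standard correlation-based feature selection heuristic:
#' `Merit = k * mean(r_cf) / sqrt(k + k (k - 1) * mean(r_ff))`,
#' where `k` is the subset size, `mean(r_cf)` averages feature-class
#' correlations over the subset and `mean(r_ff)` averages feature-feature
#' correlations over its distinct pairs.  For a singleton this reduces to
#' the feature's own class correlation.  High merit means strong class
#' association with low internal redundancy.
#'
#' @param subset Integer or character vector of feature identifiers
#'   (non-empty).
#' @param cache A `cfs_cache` from [correlation_cache()].
#' @return The merit (a non-negative number).
#' @export
cfs_merit <- function(subset, cache) {
  if (length(subset) == 0L) abort("subset must be non-empty")
  k <- length(subset)
  rcf <- mean(cache$r_cf[subset])
  if (k == 1L) return(unname(rcf))
  rff_sub <- cache$r_ff[subset, subset]
  rff <- mean(rff_sub[upper.tri(rff_sub)])
  unname(k * rcf / sqrt(k + k * (k - 1) * rff))
}

#' Best-first search over feature subsets by CFS merit
#'
#' Greedy hill climbing with backtracking: starting from the empty set,
#' the open subset with the highest merit is repeatedly expanded by every
#' single-feature addition; the search stops after `stale_limit`
#' consecutive expansions that fail to improve the best merit seen.
#' Ties are broken toward the lexicographically smallest feature-index
#' set, making the search fully deterministic for a given feature order.
#'
#' @param cache A `cfs_cache` from [correlation_cache()].
#' @param stale_limit Number of non-improving expansions tolerated before
#'   stopping; default 5 (the conventional default for this search).
#' @return A list of class `cfs_subset` with `features` (integer
#'   indices, sorted), `names` (feature names, if the cache has them) and
#'   `merit`.
#' @export
best_first_search <- function(cache, stale_limit = 5L) {
  stopifnot(stale_limit >= 1L)
  d <- length(cache$r_cf)
  key <- function(set) paste0("s", paste(set, collapse = ","))

  open_keys <- key(integer(0))
  open_sets <- list(integer(0))
  open_merits <- 0                     # merit of the empty set, by convention
  seen <- new.env(parent = emptyenv())
  assign(key(integer(0)), TRUE, envir = seen)

  best_set <- integer(0)
  best_merit <- 0
  stale <- 0L

  while (length(open_sets) > 0L && stale < stale_limit) {
    pick <- which(open_merits == max(open_merits))
    if (length(pick) > 1L) {           # lexicographically smallest key wins
      pick <- pick[order(open_keys[pick])][1]
    }
    node <- open_sets[[pick]]
    open_sets <- open_sets[-pick]
    open_merits <- open_merits[-pick]
    open_keys <- open_keys[-pick]

    improved <- FALSE
    for (f in setdiff(seq_len(d), node)) {
      child <- sort(c(node, f))
      ck <- key(child)
      if (exists(ck, envir = seen, inherits = FALSE)) next
      assign(ck, TRUE, envir = seen)
      m <- cfs_merit(child, cache)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merits <- c(open_merits, m)
      open_keys <- c(open_keys, ck)
      if (m > best_merit + 1e-12) {
        best_merit <- m
        best_set <- child
        improved <- TRUE
      } else if (abs(m - best_merit) <= 1e-12 && length(best_set) > 0L) {
        # equal merit: prefer the lexicographically smaller set
        if (ck < key(best_set)) best_set <- child
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }

  structure(list(
    features = best_set,
    names = if (!is.null(names(cache$r_cf))) names(cache$r_cf)[best_set] else NULL,
    merit = best_merit
  ), class = "cfs_subset")
}
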