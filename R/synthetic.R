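#' Configuration for the synthetic peptide generator
#'
#' The generator emulates the compositional structure observed in real
#' acetylation data: positive windows are enriched for K, R and G at the
#' flanking positions, negative windows for L, S and E, with the central
#' position always a lysine.  Residues are drawn independently per
#' position from categorical distributions: the background everywhere,
#' except at the enrichment positions where probability mass `delta` is
#' moved onto the class's enriched residues (split equally among them).
#'
#' @param n_per_class Windows generated per class, default 2000.
#' @param half_width Window half-width `n`, default 10 (window size 21).
#' @param delta Enrichment strength in `[0, 1]`, default 0.3; `delta = 0`
#'   makes the classes identically distributed (null configuration).
#' @param pos_enriched,neg_enriched Residues enriched in positive /
#'   negative windows; defaults K, R, G and L, S, E.
#' @param enrich_positions Window offsets (relative to the central K)
#'   carrying the enrichment; default `-7...-1` and `1...7`.
#' @param background `"uniform"` (default) or a named probability vector
#'   over the 20 residues.
#' @param seed Integer seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 2000L, half_width = 10L,
                             delta = 0.3,
                             pos_enriched = c("K", "R", "G"),
                             neg_enriched = c("L", "S", "E"),
                             enrich_positions = c(-7:-1, 1:7),
                             background = "uniform", seed = 1L) {
  if (identical(background, "uniform")) {
    background <- setNames(rep(1 / 20, 20), AA_ALPHABET)
  } else {
    background <- background[AA_ALPHABET]
    if (anyNA(background) || abs(sum(background) - 1) > 1e-8) {
      abort("`background` must be a probability vector over the 20 residues")
    }
  }
  stopifnot(delta >= 0, delta <= 1, half_width >= 1)
  enrich_positions <- enrich_positions[abs(enrich_positions) <= half_width &
                                         enrich_positions != 0]
  structure(list(n_per_class = as.integer(n_per_class),
                 half_width = as.integer(half_width), delta = delta,
                 pos_enriched = pos_enriched, neg_enriched = neg_enriched,
                 enrich_positions = as.integer(enrich_positions),
                 background = background, seed = as.integer(seed)),
            class = "synthetic_config")
}

# Per-position categorical distribution for one class at one offset.
position_distribution <- function(config, offset, class) {
  p <- config$background
  enriched <- if (class == 1L) config$pos_enriched else config$neg_enriched
  if (offset %in% config$enrich_positions && config$delta > 0) {
    # move delta of the total mass onto the enriched residues, scaling the
    # rest down; negative probabilities are impossible since delta <= 1
    p <- p * (1 - config$delta)
    p[enriched] <- p[enriched] + config$delta / length(enriched)
  }
  p / sum(p)
}

#' Generate labeled synthetic peptide windows
#'
#' @param config A [synthetic_config()].
#' @return A tibble of peptides (`protein_id`, `center_pos`, `window`,
#'   `n`, `label`) with exactly `n_per_class` rows per class,
#'   reproducible from the seed.
#' @export
generate_peptides <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  hw <- config$half_width
  width <- 2L * hw + 1L
  offsets <- seq.int(-hw, hw)
  one_class <- function(class, count, prefix) {
    cols <- lapply(offsets, function(o) {
      if (o == 0L) return(rep("K", count))
      sample(AA_ALPHABET, count, replace = TRUE,
             prob = position_distribution(config, o, class))
    })
    windows <- do.call(paste0, cols)
    tibble::tibble(
      protein_id = sprintf("%s%05d", prefix, seq_len(count)),
      center_pos = hw + 1L, window = windows, n = hw,
      label = rep(as.integer(class), count)
    )
  }
  dplyr::bind_rows(one_class(1L, config$n_per_class, "synpos"),
                   one_class(0L, config$n_per_class, "synneg"))
}

#' Generate synthetic proteins with planted acetylation sites
#'
#' Builds random background proteins and plants positive-class windows
#' (drawn as in [generate_peptides()]) at recorded lysine positions, so
#' the FASTA + site-annotation round trip through [extract_windows()]
#' can be exercised end to end.  Lysines arising in the background serve
#' as unannotated negatives.
#'
#' @param config A [synthetic_config()].
#' @param n_proteins Number of proteins, default 10.
#' @param sites_per_protein Planted sites per protein, default 2 —
#'   roughly the sites-per-protein density of curated acetylation data.
#' @param length_range Protein length range, default `c(300, 600)`.
#' @return A list with `proteins` (tibble `id`, `sequence`) and `sites`
#'   (tibble `protein_id`, `position`, `label = 1`).
#' @export
generate_proteins <- function(config, n_proteins = 10L,
                              sites_per_protein = 2L,
                              length_range = c(300L, 600L)) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(derive_seed(config$seed, 3L))
  hw <- config$half_width
  width <- 2L * hw + 1L
  # positive-class per-position sampling, one window at a time
  dists <- lapply(seq.int(-hw, hw), function(o) {
    if (o == 0L) NULL else position_distribution(config, o, 1L)
  })
  plant_window <- function() {
    vapply(seq_len(width), function(j) {
      if (is.null(dists[[j]])) "K"
      else sample(AA_ALPHABET, 1L, prob = dists[[j]])
    }, character(1))
  }
  proteins <- vector("list", n_proteins)
  sites <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    len <- sample(seq(length_range[1], length_range[2]), 1L)
    chars <- sample(AA_ALPHABET, len, replace = TRUE,
                    prob = config$background)
    # plant at non-overlapping centers, clear of both termini
    lo <- hw + 1L
    hi <- len - hw
    centers <- integer(0)
    candidates <- sample(seq(lo, hi))
    for (c0 in candidates) {
      if (length(centers) == sites_per_protein) break
      if (all(abs(c0 - centers) > width)) centers <- c(centers, c0)
    }
    centers <- sort(centers)
    for (c0 in centers) {
      chars[(c0 - hw):(c0 + hw)] <- plant_window()
    }
    proteins[[i]] <- tibble::tibble(id = sprintf("synprot%04d", i),
                                    sequence = paste(chars, collapse = ""))
    sites[[i]] <- tibble::tibble(protein_id = sprintf("synprot%04d", i),
                                 position = centers, label = 1L)
  }
  list(proteins = dplyr::bind_rows(proteins),
       sites = dplyr::bind_rows(sites))
}

#' Generate peptides from known class-conditional Markov chains
#'
#' Oracle generator for transition-matrix recovery tests: windows are
#' simulated residue by residue, the first from the uniform
#' distribution, each subsequent one from the class's transition matrix
#' row of its predecessor.  The central position is then overwritten
#' with K to satisfy the window invariant; for recovery statistics that
#' position should be excluded (e.g. by masking it to `X` before
#' estimation, which makes its adjacent pairs inert).
#'
#' @param t_pos,t_neg `transition_matrix` objects used as ground truth
#'   for the two classes.
#' @param n_per_class Windows per class.
#' @param half_width Window half-width.
#' @param seed Integer seed.
#' @param force_center_k Overwrite the central residue with K
#'   (default `TRUE`).
#' @return A peptide tibble as from [generate_peptides()].
#' @export
generate_markov_peptides <- function(t_pos, t_neg, n_per_class = 1000L,
                                     half_width = 10L, seed = 1L,
                                     force_center_k = TRUE) {
  set.seed(seed)
  width <- 2L * half_width + 1L
  one_class <- function(tm, class, prefix) {
    codes <- matrix(0L, nrow = n_per_class, ncol = width)
    codes[, 1] <- sample.int(20L, n_per_class, replace = TRUE)
    cum <- t(apply(tm$probs, 1, cumsum))
    for (j in 2:width) {
      # vectorized chain step: draw next residue for all windows at once
      u <- runif(n_per_class)
      prev <- codes[, j - 1L]
      codes[, j] <- max.col(cum[prev, , drop = FALSE] >= u, "first")
    }
    chars <- matrix(AA_ALPHABET[codes], nrow = n_per_class)
    if (force_center_k) chars[, half_width + 1L] <- "K"
    tibble::tibble(
      protein_id = sprintf("%s%05d", prefix, seq_len(n_per_class)),
      center_pos = half_width + 1L,
      window = apply(chars, 1, paste, collapse = ""),
      n = half_width, label = rep(as.integer(class), n_per_class)
    )
  }
  dplyr::bind_rows(one_class(t_pos, 1L, "mkpos"),
                   one_class(t_neg, 0L, "mkneg"))
}
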