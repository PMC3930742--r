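test_that("generation is seeded, balanced and K-centered", {
  cfg <- synthetic_config(n_per_class = 100, seed = 26)
  a <- generate_peptides(cfg)
  b <- generate_peptides(cfg)
  expect_identical(a, b)                           # byte-for-byte reproducible
  expect_equal(sum(a$label == 1), 100L)
  expect_equal(sum(a$label == 0), 100L)
  expect_true(all(substr(a$window, 11, 11) == "K"))
  expect_true(all(nchar(a$window) == 21L))
})

test_that("a null configuration produces identically distributed classes", {
  cfg <- synthetic_config(n_per_class = 2000, delta = 0, seed = 27)
  pep <- generate_peptides(cfg)
  m <- acepred:::window_char_matrix(pep$window)
  col <- 11 - 3
  fpos <- mean(m[pep$label == 1, col] %in% c("K", "R", "G"))
  fneg <- mean(m[pep$label == 0, col] %in% c("K", "R", "G"))
  expect_lt(abs(fpos - fneg), 0.05)
})

test_that("enrichment shifts flank composition by about delta", {
  cfg <- synthetic_config(n_per_class = 2000, delta = 0.3, seed = 12)
  pep <- generate_peptides(cfg)
  m <- acepred:::window_char_matrix(pep$window)
  col <- 11 - 3                                    # offset -3, an enriched position
  fpos <- mean(m[pep$label == 1, col] %in% c("K", "R", "G"))
  fneg <- mean(m[pep$label == 0, col] %in% c("K", "R", "G"))
  expect_gte(fpos - fneg, 0.15)
  # outside the enrichment band the classes match
  col0 <- 11 - 9
  fpos0 <- mean(m[pep$label == 1, col0] %in% c("K", "R", "G"))
  fneg0 <- mean(m[pep$label == 0, col0] %in% c("K", "R", "G"))
  expect_lt(abs(fpos0 - fneg0), 0.05)
})

test_that("empirical per-position frequencies converge to the configuration", {
  cfg <- synthetic_config(n_per_class = 5000, delta = 0.3, seed = 28)
  pep <- generate_peptides(cfg)
  freq <- positional_frequencies(pep[pep$label == 1, ], pseudocount = 0)
  for (off in c(-3, 5)) {                          # enriched positions
    want <- acepred:::position_distribution(cfg, off, 1L)
    got <- freq[, as.character(off)]
    expect_lt(max(abs(got - want)), 0.03)
  }
  off_bg <- -9                                     # background position
  want_bg <- cfg$background
  expect_lt(max(abs(freq[, as.character(off_bg)] - want_bg)), 0.03)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(delta = 1.5))
  expect_error(synthetic_config(background = setNames(rep(0.1, 20),
                                                      aa_alphabet())),
               "probability vector")
})

test_that("planted proteins record sites at lysines and round-trip windows", {
  cfg <- synthetic_config(half_width = 6, enrich_positions = c(-4:-1, 1:4),
                          seed = 29)
  sim <- generate_proteins(cfg, n_proteins = 10, sites_per_protein = 3,
                           length_range = c(120, 200))
  expect_equal(nrow(sim$sites), 30L)
  chars <- strsplit(sim$proteins$sequence, "")
  names(chars) <- sim$proteins$id
  for (i in seq_len(nrow(sim$sites))) {
    expect_equal(chars[[sim$sites$protein_id[i]]][sim$sites$position[i]], "K")
  }
  # extracting at the planted positions reproduces embedded windows exactly
  w <- extract_windows(sim$proteins, n = 6, sites = sim$sites)
  expect_equal(nrow(w), 30L)
  for (i in seq_len(nrow(w))) {
    seq_i <- sim$proteins$sequence[sim$proteins$id == w$protein_id[i]]
    expect_equal(w$window[i],
                 substr(seq_i, w$center_pos[i] - 6, w$center_pos[i] + 6))
  }
  # without annotations, extracted windows carry unknown labels
  wu <- extract_windows(sim$proteins, n = 6)
  expect_true(all(is.na(wu$label)))
})

test_that("Markov generation follows the chain and respects the center", {
  # degenerate chain: every row points to A
  P <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  P[, "A"] <- 1
  tm <- structure(list(probs = P, counts = NULL, pseudocount = 0),
                  class = "transition_matrix")
  pep <- generate_markov_peptides(tm, tm, n_per_class = 5, half_width = 3,
                                  seed = 30)
  core <- paste0(substr(pep$window, 2, 3), substr(pep$window, 5, 7))
  expect_true(all(core == "AAAAA"))
  expect_true(all(substr(pep$window, 4, 4) == "K"))
  pep2 <- generate_markov_peptides(tm, tm, n_per_class = 5, half_width = 3,
                                   seed = 30, force_center_k = FALSE)
  expect_true(all(substr(pep2$window, 2, 7) == "AAAAAA"))
})

test_that("pipeline accuracy grows with the enrichment strength", {
  aa <- fixture_aaindex()
  accs <- vapply(c(0, 0.15, 0.3), function(d) {
    cfg <- synthetic_config(n_per_class = 600, delta = d, seed = 21)
    pep <- generate_peptides(cfg)
    kfold_cv(pep, aaindex = aa, k = 5, seed = 3)$pooled$Acc
  }, numeric(1))
  expect_true(all(diff(accs) >= -0.02))            # non-strict monotone growth
  expect_gt(accs[3], accs[1] + 0.2)
})
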