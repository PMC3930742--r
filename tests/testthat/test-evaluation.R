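test_that("confusion counts follow the threshold rule", {
  expect_equal(confusion(c(1, 0), c(0.9, 0.1)),
               tibble::tibble(TP = 1L, FP = 0L, TN = 1L, FN = 0L))
  expect_equal(confusion(c(1, 0), c(0.1, 0.9)),
               tibble::tibble(TP = 0L, FP = 1L, TN = 0L, FN = 1L))
  expect_equal(confusion(c(1, 1, 1, 0, 0), rep(1, 5)),
               tibble::tibble(TP = 3L, FP = 2L, TN = 0L, FN = 0L))
  expect_error(confusion(c(1, 0), 0.5), "same length")
})

test_that("metrics reproduce hand-computed values and conventions", {
  perfect <- compute_metrics(tibble::tibble(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(Sn = 1, Sp = 1, Acc = 1, MCC = 1))

  m <- compute_metrics(tibble::tibble(TP = 68, FN = 32, TN = 70, FP = 30))
  expect_equal(m$Sn, 0.68)
  expect_equal(m$Sp, 0.70)
  expect_equal(m$Acc, 0.69)
  expect_equal(m$MCC, 3800 / sqrt(98 * 100 * 100 * 102))
  expect_equal(m$MCC, 0.3801, tolerance = 1e-4)

  # all-positive predictor on balanced data: MCC zero-denominator convention
  allpos <- compute_metrics(tibble::tibble(TP = 40, FP = 40, TN = 0, FN = 0))
  expect_equal(unlist(allpos), c(Sn = 1, Sp = 0, Acc = 0.5, MCC = 0))
  expect_error(compute_metrics(tibble::tibble(TP = 0, FP = 0, TN = 0, FN = 0)),
               "all counts are zero")
})

test_that("metrics agree with a brute-force recount on random instances", {
  set.seed(19)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    y <- rbinom(n, 1, 0.5)
    p <- runif(n)
    cc <- confusion(y, p, 0.5)
    pred <- as.integer(p >= 0.5)
    expect_equal(cc$TP, sum(y == 1 & pred == 1))
    expect_equal(cc$TN, sum(y == 0 & pred == 0))
    expect_equal(cc$FP, sum(y == 0 & pred == 1))
    expect_equal(cc$FN, sum(y == 1 & pred == 0))
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, n)
    m <- compute_metrics(cc)
    if (sum(y) > 0 && sum(1 - y) > 0) {
      expect_equal(m$Acc, mean(pred == y))
    }
    # MCC is symmetric under swapping the two classes
    swapped <- compute_metrics(tibble::tibble(TP = cc$TN, TN = cc$TP,
                                              FP = cc$FN, FN = cc$FP))
    expect_equal(m$MCC, swapped$MCC)
  }
})

test_that("stratified folds partition the data and preserve determinism", {
  cfg <- synthetic_config(n_per_class = 150, half_width = 5, seed = 22)
  pep <- generate_peptides(cfg)
  aa <- fixture_aaindex()
  cv1 <- kfold_cv(pep, aaindex = aa, k = 5, seed = 4)
  cv2 <- kfold_cv(pep, aaindex = aa, k = 5, seed = 4)
  expect_identical(cv1$folds, cv2$folds)
  # folds disjoint and covering: per-fold counts sum to the total
  expect_equal(sum(cv1$folds$TP + cv1$folds$FP + cv1$folds$TN + cv1$folds$FN),
               nrow(pep))
  # stratification: each fold holds 30 positives and 30 negatives
  expect_equal(unique(cv1$folds$TP + cv1$folds$FN), 30L)
  expect_equal(unique(cv1$folds$TN + cv1$folds$FP), 30L)
  # micro-averaging identity
  expect_equal(cv1$pooled$Acc,
               sum(cv1$folds$TP + cv1$folds$TN) / nrow(pep))
})

test_that("balanced resampling emits one row per iteration with derived seeds", {
  cfg <- synthetic_config(n_per_class = 60, half_width = 4,
                          enrich_positions = c(-3:-1, 1:3), seed = 23)
  pep <- generate_peptides(cfg)
  pos <- pep[pep$label == 1, ]
  pool <- dplyr::bind_rows(pep[pep$label == 0, ],
                           dplyr::mutate(pep[pep$label == 0, ],
                                         protein_id = paste0(protein_id, "b")))
  res <- balanced_resampling_cv(pos, pool, iterations = 10, k = 5, seed = 9,
                                features = "pssc")
  expect_equal(nrow(res$iterations), 10L)
  expect_equal(res$iterations$iteration, 1:10)
  expect_equal(res$summary$statistic, c("mean", "sd"))
  expect_equal(glance(res)$Acc, mean(res$iterations$Acc))

  # a pool exactly the size of the positive set leaves no sampling freedom
  res0 <- balanced_resampling_cv(pos, pep[pep$label == 0, ], iterations = 3,
                                 k = 5, seed = 9, features = "pssc")
  expect_equal(res0$summary$Acc[res0$summary$statistic == "sd"], 0)

  expect_error(balanced_resampling_cv(pos, pos[1:10, ], iterations = 2, k = 2),
               "smaller than the positive set")
})

test_that("different master seeds draw different negative subsets", {
  cfg <- synthetic_config(n_per_class = 40, half_width = 3,
                          enrich_positions = c(-2, -1, 1, 2), seed = 24)
  pep <- generate_peptides(cfg)
  pos <- pep[pep$label == 1, ][1:10, ]
  pool <- pep[pep$label == 0, ]
  r1 <- balanced_resampling_cv(pos, pool, iterations = 2, k = 2, seed = 1,
                               features = "pssc")
  r2 <- balanced_resampling_cv(pos, pool, iterations = 2, k = 2, seed = 2,
                               features = "pssc")
  # different master seeds (and different iterations) draw different members
  expect_false(setequal(r1$draws[[1]]$protein_id, r2$draws[[1]]$protein_id))
  expect_false(setequal(r1$draws[[1]]$protein_id, r1$draws[[2]]$protein_id))
})

test_that("a single-n window scan reproduces the resampling result", {
  cfg <- synthetic_config(half_width = 5, enrich_positions = c(-4:-1, 1:4),
                          delta = 0.4, seed = 25)
  sim <- generate_proteins(cfg, n_proteins = 40, sites_per_protein = 2,
                           length_range = c(150, 250))
  aa <- fixture_aaindex()
  tab <- window_scan(sim$proteins, sim$sites, n_values = 5, aaindex = aa,
                     iterations = 1, k = 5, seed = 6)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$window_size, 11L)

  windows <- extract_windows(sim$proteins, n = 5)
  key <- paste(windows$protein_id, windows$center_pos)
  windows$label <- ifelse(key %in% paste(sim$sites$protein_id,
                                         sim$sites$position), 1L, 0L)
  res <- balanced_resampling_cv(windows[windows$label == 1, ],
                                windows[windows$label == 0, ],
                                iterations = 1, k = 5,
                                seed = acepred:::derive_seed(6, 13L, 5L),
                                aaindex = aa)
  expect_equal(tab$Acc, glance(res)$Acc)
  expect_equal(tab$MCC, glance(res)$MCC)
})

test_that("percentage tables are written in the published layout", {
  tab <- tibble::tibble(label = "21", Sn = 0.6801, Sp = 0.6995,
                        Acc = 0.6898, MCC = 0.3797)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metrics_table(tab, path)
  lines <- readLines(path)
  expect_match(lines[1], "Sn \\(%\\)")
  expect_match(lines[2], "68.01", fixed = TRUE)
  expect_match(lines[2], "37.97", fixed = TRUE)
})
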