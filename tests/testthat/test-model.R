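trained_toy_model <- function(seed = 31, n_per_class = 200, half_width = 5) {
  cfg <- synthetic_config(n_per_class = n_per_class, half_width = half_width,
                          enrich_positions = c(-4:-1, 1:4), seed = seed)
  pep <- generate_peptides(cfg)
  list(model = train_model(pep, aaindex = fixture_aaindex()), peptides = pep)
}

test_that("featurization is pure and lays features out deterministically", {
  tt <- trained_toy_model()
  X1 <- featurize(tt$peptides, tt$model)
  X2 <- featurize(tt$peptides, tt$model)
  expect_identical(X1, X2)
  k <- nrow(tt$model$aaindex)
  expect_equal(ncol(X1), k + 2L)
  expect_equal(colnames(X1),
               c(tt$model$aaindex$accession, "tpm_score", "pssc_score"))
  expect_true(all(X1[, seq_len(k)] >= 0 & X1[, seq_len(k)] <= 1))
})

test_that("symmetric pipeline state zeroes the sequence scores", {
  tt <- trained_toy_model()
  model <- tt$model
  model$t_neg <- model$t_pos                       # equal class chains
  zero <- unclass(model$pssc)
  zero[] <- 0
  model$pssc <- structure(zero, class = c("pssc_matrix", "matrix"),
                          r = attr(tt$model$pssc, "r"))
  X <- featurize(tt$peptides[1:10, ], model)
  expect_equal(unname(X[, "tpm_score"]), rep(0, 10))
  expect_equal(unname(X[, "pssc_score"]), rep(0, 10))
})

test_that("prediction attaches probabilities and thresholded calls", {
  tt <- trained_toy_model()
  pred <- predict(tt$model, tt$peptides)
  expect_true(all(pred$probability > 0 & pred$probability < 1))
  expect_equal(pred$predicted, as.integer(pred$probability >= 0.5))
  expect_gt(mean(pred$predicted[pred$label == 1]),
            mean(pred$predicted[pred$label == 0]))
  # window length must match the frozen pipeline
  expect_error(predict(tt$model, make_peptides("AKA")), "does not match")
})

test_that("tidy and glance summarize a trained model", {
  tt <- trained_toy_model()
  td <- tidy(tt$model)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), length(tt$model$feature_names) + 1L)
  gl <- glance(tt$model)
  expect_equal(gl$window_size, 11L)
  expect_true(gl$converged)
})

test_that("a model archive round-trips predictions bit-for-bit", {
  tt <- trained_toy_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(tt$model, path)
  back <- read_model(path)
  expect_equal(back$n, tt$model$n)
  expect_identical(back$coef, tt$model$coef)
  expect_identical(back$t_pos$probs, tt$model$t_pos$probs)
  expect_identical(unclass(back$pssc), unclass(tt$model$pssc),
                   ignore_attr = TRUE)
  p1 <- predict(tt$model, tt$peptides)$probability
  p2 <- predict(back, tt$peptides)$probability
  expect_identical(p1, p2)
})

test_that("the model without AAPP trains on sequence scores alone", {
  cfg <- synthetic_config(n_per_class = 150, half_width = 4,
                          enrich_positions = c(-3:-1, 1:3), seed = 32)
  pep <- generate_peptides(cfg)
  m <- train_model(pep, features = c("tpm", "pssc"))
  expect_equal(m$feature_names, c("tpm_score", "pssc_score"))
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(predict(back, pep)$probability,
                   predict(m, pep)$probability)
})

test_that("the CLI chains simulate, train and predict end to end", {
  out <- withr::local_tempdir()
  sim_dir <- file.path(out, "sim")
  train_dir <- file.path(out, "fit")
  pred_dir <- file.path(out, "pred")
  args_common <- c("--n", "6", "--seed", "5")
  expect_equal(suppressMessages(run_cli(c(
    "simulate", "--out", sim_dir, "--n-proteins", "30", "--delta", "0.4",
    args_common))), 0L)
  expect_true(file.exists(file.path(sim_dir, "proteins.fasta")))
  expect_true(file.exists(file.path(sim_dir, "config.txt")))

  expect_equal(suppressMessages(run_cli(c(
    "train", "--out", train_dir,
    "--fasta", file.path(sim_dir, "proteins.fasta"),
    "--sites", file.path(sim_dir, "sites.tsv"), args_common))), 0L)
  model_path <- file.path(train_dir, "model.txt")
  expect_true(file.exists(model_path))

  expect_equal(suppressMessages(run_cli(c(
    "predict", "--out", pred_dir, "--model", model_path,
    "--fasta", file.path(sim_dir, "proteins.fasta")))), 0L)
  pred <- utils::read.table(file.path(pred_dir, "predictions.tsv"),
                            sep = "\t", header = TRUE)
  expect_gt(nrow(pred), 0L)
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))

  # re-running training with the same config echo reproduces the model
  train_dir2 <- file.path(out, "fit2")
  expect_equal(suppressMessages(run_cli(c(
    "train", "--out", train_dir2,
    "--fasta", file.path(sim_dir, "proteins.fasta"),
    "--sites", file.path(sim_dir, "sites.tsv"), args_common))), 0L)
  expect_identical(readLines(model_path),
                   readLines(file.path(train_dir2, "model.txt")))

  # a window mismatch at prediction time is surfaced as a failure
  expect_equal(suppressMessages(run_cli(c(
    "predict", "--out", pred_dir, "--model", model_path,
    "--fasta", file.path(sim_dir, "proteins.fasta"), "--n", "9"))), 1L)
})

test_that("the CLI reports usage errors with exit code 2", {
  expect_equal(suppressMessages(run_cli(character())), 2L)
  expect_equal(suppressMessages(run_cli(c("frobnicate", "--out", tempdir()))), 2L)
  expect_equal(suppressMessages(run_cli(c("simulate"))), 2L)
})

test_that("the cv subcommand writes one row per resampling iteration", {
  out <- withr::local_tempdir()
  sim_dir <- file.path(out, "sim")
  cv_dir <- file.path(out, "cv")
  expect_equal(suppressMessages(run_cli(c(
    "simulate", "--out", sim_dir, "--n-proteins", "40", "--delta", "0.4",
    "--n", "5", "--seed", "8"))), 0L)
  expect_equal(suppressMessages(run_cli(c(
    "cv", "--out", cv_dir, "--fasta", file.path(sim_dir, "proteins.fasta"),
    "--sites", file.path(sim_dir, "sites.tsv"),
    "--n", "5", "--k", "4", "--iterations", "3", "--seed", "8"))), 0L)
  iters <- utils::read.table(file.path(cv_dir, "cv_iterations.tsv"),
                             sep = "\t", header = TRUE)
  expect_equal(nrow(iters), 3L)
})
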