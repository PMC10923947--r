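# Noiseless tiling population: cell i's activity is a deterministic bump
# of linear position, identical on every run.
tiling_activity <- function(runs, n_cells = 50) {
  n_frames <- max(unlist(lapply(runs, `[[`, "frames")))
  act <- matrix(0, n_cells, n_frames)
  centers <- (seq_len(n_cells) - 0.5) / n_cells
  for (r in runs)
    for (ci in seq_len(n_cells))
      act[ci, r$frames] <- exp(-0.5 * ((r$u - centers[ci]) / 0.05)^2)
  act
}

test_that("position decoder recovers a separable tiling code", {
  b <- fix_behavior()
  runs <- segment_runs(b$track, b$trials)
  act <- tiling_activity(runs)
  dec <- train_position_decoder(act, runs, "left")
  res <- decode_position(dec, act, runs)
  expect_lt(res$mae, 0.02)
  expect_true(all(res$truth >= 0 & res$truth <= 1))

  # directions are never mixed: the model carries its direction and only
  # decodes same-direction runs
  expect_equal(dec$direction, "left")
  n_left_frames <- length(unlist(lapply(
    runs[vapply(runs, `[[`, "", "direction") == "left"], `[[`, "frames")))
  expect_equal(length(res$predictions), n_left_frames)

  expect_error(decode_position(dec, act[1:10, ], runs), "mismatch")
  expect_error(train_position_decoder(act, runs[1:2], "left"), ">= 2 runs")
})

test_that("outcome decoder separates side-selective cells and calibrates", {
  set.seed(14)
  n_tr <- 40
  labels <- rep(c("left", "right"), each = n_tr / 2)
  # two perfectly side-selective noiseless cells
  feats <- cbind(ifelse(labels == "left", 2, 0),
                 ifelse(labels == "right", 2, 0))
  m <- train_outcome_decoder(feats, labels)
  out <- decode_outcome(m, feats, labels, n_shuffle = 100, seed = 1)
  expect_equal(out$accuracy, 1)
  expect_lt(abs(out$shuffle_accuracy - 0.5), 3 * sqrt(0.25 / n_tr))

  # class-constant features: accuracy equals the majority-class rate
  lab2 <- c(rep("left", 25), rep("right", 15))
  const <- matrix(1, 40, 3)
  m2 <- train_outcome_decoder(const, lab2)
  out2 <- decode_outcome(m2, const, lab2, n_shuffle = 0)
  expect_equal(out2$accuracy, 25 / 40)

  expect_error(train_outcome_decoder(feats, rep("left", 40)), "both classes")

  # fitted decoder is deterministic
  m3 <- train_outcome_decoder(feats, labels)
  expect_identical(as.numeric(coef(m$fit)), as.numeric(coef(m3$fit)))
})

test_that("leave-one-out decoding is exact on separable data, chance on shuffled", {
  set.seed(15)
  labels <- rep(c("left", "right"), 20)
  feats <- cbind(ifelse(labels == "left", 1, -1) + rnorm(40, 0, 0.05),
                 rnorm(40, 0, 0.05))
  expect_equal(loo_outcome_decoding(feats, labels, n_iter = 60, seed = 2), 1)
  null <- loo_outcome_decoding(feats, labels, n_iter = 200, shuffle = TRUE,
                               seed = 3)
  expect_lt(abs(null - 0.5), 0.12)
  expect_identical(loo_outcome_decoding(feats, labels, n_iter = 30, seed = 4),
                   loo_outcome_decoding(feats, labels, n_iter = 30, seed = 4))
  expect_error(loo_outcome_decoding(feats[1:2, ], labels[1:2], seed = 1),
               ">= 3 trials")
})

test_that("single-cell decoding tracks side selectivity", {
  set.seed(16)
  n_tr <- 40
  labels <- rep(c("left", "right"), n_tr / 2)
  seps <- c(2, 1.2, 0.6, 0.3, 0)       # graded selectivity
  feats <- vapply(seps, function(s)
    1 + ifelse(labels == "left", s / 2, -s / 2) + rnorm(n_tr, 0, 0.15),
    numeric(n_tr))
  res <- single_cell_decoding(feats, labels, activity_threshold = 0.5)
  expect_equal(res$n_excluded, 0)
  expect_equal(res$accuracy[1], 1)                   # |S| ~ 1, noiseless-ish
  expect_lt(abs(res$accuracy[5] - 0.5), 0.22)        # untuned cell ~ chance
  expect_gt(cor(seps, res$accuracy, method = "spearman"), 0.8)

  # sub-threshold cells are excluded and counted
  feats2 <- cbind(feats, 0.1)
  res2 <- single_cell_decoding(feats2, labels, activity_threshold = 0.5)
  expect_equal(res2$n_excluded, 1)
  expect_true(is.na(res2$accuracy[6]))
})

test_that("subset-size curves grow toward the full-population accuracy", {
  set.seed(17)
  n_tr <- 40
  labels <- rep(c("left", "right"), n_tr / 2)
  p <- 12
  sep <- seq(0.1, 1, length.out = p)
  feats <- vapply(sep, function(s)
    ifelse(labels == "left", s, -s) + rnorm(n_tr, 0, 0.6), numeric(n_tr))
  te_labels <- rep(c("left", "right"), n_tr / 2)
  te <- vapply(sep, function(s)
    ifelse(te_labels == "left", s, -s) + rnorm(n_tr, 0, 0.6), numeric(n_tr))
  curve <- subset_size_curve(feats, labels, te, te_labels,
                             sizes = c(1, 4, 12), n_draws = 15, seed = 5)
  full <- decode_outcome(train_outcome_decoder(feats, labels), te,
                         te_labels, n_shuffle = 0)$accuracy
  expect_equal(curve$accuracy[3], full)       # full population: exact match
  expect_gt(curve$accuracy[3], curve$accuracy[1])
  expect_error(subset_size_curve(feats, labels, te, te_labels, sizes = 20,
                                 n_draws = 2, seed = 1), "exceeds")
})

test_that("outcome decoding transfers across drift-free synthetic days", {
  s <- fix_two_days()$sessions
  f1 <- outcome_features(s[[1]])
  f2 <- outcome_features(s[[2]])
  m <- train_outcome_decoder(f1$features, f1$labels)
  acc <- decode_outcome(m, f2$features, f2$labels, n_shuffle = 50,
                        seed = 6)
  expect_gt(acc$accuracy, 0.8)
  expect_lt(abs(acc$shuffle_accuracy - 0.5), 0.25)

  # pre-divergence features are computable and preserve trial count
  fd <- outcome_features(s[[1]], until_divergence = TRUE)
  expect_equal(dim(fd$features), dim(f1$features))
})
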