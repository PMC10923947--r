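# Shared design built once from the fixture session.
fix_design <- function() cached("glm_design", function() {
  s <- fix_two_days()$sessions[[1]]
  build_design(s)
})

# Response constructed as an exact function of a design factor plus noise.
factor_response <- function(design, predictor, gains, noise_sd = 0,
                            seed = 1) {
  set.seed(seed)
  y <- gains[as.integer(design[[predictor]])]
  if (noise_sd > 0) y <- y + rnorm(design$n, 0, noise_sd)
  y
}

test_that("the encoding design holds 8 position, 4 speed and 2 goal levels", {
  d <- fix_design()
  expect_s3_class(d, "glm_design")
  expect_equal(nlevels(d$pos), 8)
  expect_equal(sort(unique(as.integer(d$pos))), 1:8)
  expect_equal(nlevels(d$speed), 4)
  expect_equal(nlevels(d$goal), 2)
  expect_equal(length(d$pos), d$n)

  # speed quartiles split frames into near-equal quarters
  cnt <- table(d$speed)
  expect_lt(max(abs(cnt - d$n / 4)), 2)

  # goal is constant within each trial's frames
  s <- fix_two_days()$sessions[[1]]
  runs <- segment_runs(s$track, s$trials)
  off <- 0
  for (r in runs) {
    expect_equal(length(unique(d$goal[off + seq_along(r$frames)])), 1)
    off <- off + length(r$frames)
  }
})

test_that("cross-validated r2 is ~1 for exact factor responses, ~0 for noise", {
  d <- fix_design()
  y <- factor_response(d, "pos", gains = seq(0, 3.5, by = 0.5))
  r2 <- fit_cv_glm(d, y, seed = 2)
  expect_gte(r2, 0.99)

  set.seed(3)
  Y_noise <- matrix(rnorm(d$n * 100), d$n, 100)
  r2n <- fit_cv_glm(d, Y_noise, seed = 4)
  expect_lt(mean(r2n), 0.02)

  # the fold assignment partitions all chunks exactly once
  folds <- driftframe:::cv_folds(d$n, d$frame_rate, 5, 10, seed = 5)
  expect_equal(length(folds), d$n)
  expect_equal(sort(unique(folds)), 1:10)
  chunk_len <- round(5 * d$frame_rate)
  chunk_id <- (seq_len(d$n) - 1) %/% chunk_len
  expect_true(all(tapply(folds, chunk_id, function(f)
    length(unique(f))) == 1))
})

test_that("variance partitioning attributes r2 to the driving predictor", {
  d <- fix_design()
  y_pos <- factor_response(d, "pos", gains = seq(0, 3.5, by = 0.5),
                           noise_sd = 0.3)
  pv <- partition_variance(d, y_pos, seed = 6)
  expect_gt(pv$r2_full, 0.5)
  expect_gt(pv$r2_single["pos", 1], 0.9 * pv$r2_full)
  # residual single-model r2 for speed/goal reflects chance day structure
  # in a ~24-trial session; it must stay far below the position model
  expect_lt(pv$r2_single["speed", 1], 0.3 * pv$r2_single["pos", 1])
  expect_lt(pv$r2_single["goal", 1], 0.3 * pv$r2_single["pos", 1])
  # shifting the position predictor collapses most of the full model's r2
  # (trials are quasi-periodic, so a circular time shift keeps a sliver)
  expect_gt(pv$dr2_shifted["pos", 1], 0.5 * pv$r2_full)
  expect_gt(pv$dr2_shifted["pos", 1], 5 * abs(pv$dr2_shifted["speed", 1]))
  expect_lt(abs(pv$dr2_shifted["speed", 1]), 0.1)

  # additive position + speed cell: both contributions detected, ordered
  # by the injected gains
  y_two <- factor_response(d, "pos", gains = seq(0, 3.5, by = 0.5),
                           noise_sd = 0.3, seed = 7) +
    factor_response(d, "speed", gains = c(0, 0.4, 0.8, 1.2), seed = 8)
  pv2 <- partition_variance(d, y_two, seed = 9)
  expect_gt(pv2$r2_single["pos", 1], 0.2)
  expect_gt(pv2$r2_single["speed", 1], 0.03)
  expect_gt(pv2$r2_single["pos", 1], pv2$r2_single["speed", 1])
  expect_gt(pv2$r2_single["speed", 1], pv2$r2_single["goal", 1])
})

test_that("full-model r2 dominates single models on a mixed population", {
  d <- fix_design()
  s <- fix_two_days()$sessions[[1]]
  Y <- t(s$z[, d$frames, drop = FALSE])
  pv <- partition_variance(d, Y, seed = 10)
  for (p in c("pos", "speed", "goal"))
    expect_gte(mean(pv$r2_full) - mean(pv$r2_single[p, ]), -0.01)
})

test_that("permutation significance flags driven cells, spares noise cells", {
  d <- fix_design()
  set.seed(11)
  y_pos <- vapply(1:6, function(i)
    factor_response(d, "pos", gains = seq(0, 3.5, by = 0.5),
                    noise_sd = 0.5, seed = 20 + i), numeric(d$n))
  y_noise <- matrix(rnorm(d$n * 6), d$n, 6)
  sig <- cell_significance(d, cbind(y_pos, y_noise), n_shuffle = 60,
                           seed = 12)
  expect_true(all(sig$flags["pos", 1:6]))          # strong position cells
  expect_lte(sum(sig$flags["pos", 7:12]), 1)       # noise cells ~ nominal
  expect_true(all(dim(sig$flags) == c(3, 12)))
  # flags are reproducible under the same seed
  sig2 <- cell_significance(d, cbind(y_pos, y_noise), n_shuffle = 60,
                            seed = 12)
  expect_identical(sig$flags, sig2$flags)

  # a cell driven by all three predictors collects all three flags
  y_all <- factor_response(d, "pos", gains = seq(0, 3.5, by = 0.5),
                           noise_sd = 0.2, seed = 30) +
    factor_response(d, "speed", gains = c(0, 1, 2, 3), seed = 31) +
    factor_response(d, "goal", gains = c(0, 2), seed = 32)
  sig3 <- cell_significance(d, y_all, n_shuffle = 60, seed = 13)
  expect_true(all(sig3$flags[, 1]))
})
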