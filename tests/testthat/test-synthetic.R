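test_that("maze trajectories are deterministic, correctly sized and epoch-tiled", {
  b1 <- simulate_maze_trajectories(n_trials = 12, seed = 3)
  b2 <- simulate_maze_trajectories(n_trials = 12, seed = 3)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$trials), 12)
  expect_equal(nrow(b1$track), max(b1$trials$end_frame))

  # epochs tile each trial without gaps
  tr <- b1$trials
  expect_true(all(tr$samp_end >= tr$start_frame))
  expect_true(all(tr$run_start == tr$samp_end + 1))
  expect_true(all(tr$center_end >= tr$run_start - 1))
  expect_true(all(tr$run_end > tr$center_end))
  expect_true(all(tr$end_frame >= tr$run_end))
  expect_true(all(tr$start_frame[-1] == tr$end_frame[-nrow(tr)] + 1))

  # left/right mix reproduces the same seeded binomial draw as a direct
  # oracle on the RNG stream
  b <- simulate_maze_trajectories(n_trials = 40, p_left = 0.5, seed = 1)
  oracle <- local({ set.seed(1); sum(runif(40) < 0.5) })
  expect_equal(sum(b$trials$choice == "left"), oracle)

  expect_error(simulate_maze_trajectories(n_trials = 1, seed = 1),
               "n_trials")
})

test_that("forced one-sided sessions starve the other direction downstream", {
  b <- simulate_maze_trajectories(n_trials = 2, p_left = 1, seed = 5)
  expect_true(all(b$trials$choice == "left"))
  runs <- segment_runs(b$track, b$trials)
  expect_error(tuning_function(rep(1, nrow(b$track)), runs, "right"),
               "no runs")
})

test_that("cross-day drift states follow the step model and its limits", {
  cells <- ground_truth_cells(20, seed = 1)
  cfg0 <- drift_config(p_drift = 0, n_sessions = 5)
  expect_true(all(apply_cross_day_drift(cells, cfg0, seed = 2) == 0))

  cfg1 <- drift_config(p_drift = 1, n_sessions = 5)
  sh <- apply_cross_day_drift(cells, cfg1, seed = 2)
  expect_true(all(sh == matrix(0:4, nrow(cells), 5, byrow = TRUE)))

  # binomial expectation at p = 0.5 over a large population
  cellsL <- ground_truth_cells(10000, seed = 3)
  shL <- apply_cross_day_drift(cellsL,
                               drift_config(p_drift = 0.5, n_sessions = 2),
                               seed = 4)
  expect_lt(abs(mean(shL[, 2] != 0) - 0.5), 0.011)

  # regularization: beyond 10 cumulative bins steps become random +-1
  cfgR <- drift_config(p_drift = 1, n_sessions = 14)
  shR <- apply_cross_day_drift(ground_truth_cells(200, seed = 5), cfgR,
                               seed = 6)
  expect_true(all(shR[, 11] == 10))
  expect_true(all(shR[, 12] == 11))          # limit reached after step 11
  expect_true(all(shR[, 13] %in% c(10, 12))) # next step random +-1
  expect_true(any(shR[, 13] == 10) && any(shR[, 13] == 12))
})

test_that("per-day drift steps scale with elapsed days when configured", {
  cells <- ground_truth_cells(4000, seed = 1)
  cfg <- drift_config(p_drift = 0.2, n_sessions = 2, per_day = TRUE)
  # a pause pair 7 days apart takes 7 steps, like 7 consecutive days
  sh_pause <- apply_cross_day_drift(cells, cfg, days = c(1, 8), seed = 9)
  expect_lt(abs(mean(sh_pause[, 2]) - 7 * 0.2), 0.1)
  cfg8 <- drift_config(p_drift = 0.2, n_sessions = 8, per_day = TRUE)
  sh_cont <- apply_cross_day_drift(cells, cfg8, days = 1:8, seed = 10)
  expect_lt(abs(mean(sh_cont[, 8]) - mean(sh_pause[, 2])), 0.15)
})

test_that("synthesized sessions honor the forward model's edge cases", {
  b <- fix_behavior()
  silent <- ground_truth_cells(1, amplitude = 0, seed = 1)
  s0 <- synthesize_session(silent, b, trace_noise_sd = 0.1, seed = 2)
  p0 <- preprocess_session(s0)
  # amplitude 0: trace is pure noise; the 3-sigma / 0.2-s rule admits
  # essentially no transients (iid-noise false-positive rate ~ p^4 per frame)
  expect_lte(nrow(p0$transients[[1]]), 1)

  oneside <- ground_truth_cells(1, direction_bias = 1, seed = 3)
  oneside$gain_left <- 1; oneside$gain_right <- 0
  oneside$field_center <- 0.5   # mid-run field: kernel decays before the
  oneside$field_center_right <- 0.5   # next trial's run begins
  b_gap <- simulate_maze_trajectories(n_trials = 24, samp_frames = 40,
                                      reward_frames = 40, seed = 7)
  s1 <- preprocess_session(
    synthesize_session(oneside, b_gap, trace_noise_sd = 0.05, seed = 4))
  st <- session_cell_stats(s1)
  expect_equal(st$side_index[1], 1)

  # identical seeds reproduce the session bit-identically
  cells <- ground_truth_cells(3, seed = 5)
  sa <- synthesize_session(cells, b, seed = 6)
  sb <- synthesize_session(cells, b, seed = 6)
  expect_identical(sa, sb)

  expect_error(synthesize_session(cells, b, trace_noise_sd = -1, seed = 1),
               "trace_noise_sd")
})

test_that("drift-free repeat sessions give cross-day tuning r of 1", {
  b <- fix_behavior()
  cells <- ground_truth_cells(8, seed = 11)
  s <- preprocess_session(synthesize_session(cells, b, seed = 12))
  tun <- session_tuning(s)
  expect_equal(cross_day_correlation(tun, tun)$pooled, 1)
})

test_that("experiment-level dropout matches the closed-form expectation", {
  # P(active all 13 days) = 0.8^13; count averaged over seeds
  counts <- vapply(1:3, function(sd) {
    ex <- generate_experiment(n_cells = 100, n_sessions = 13, n_trials = 2,
                              active_prob = 0.8, seed = 100 + sd)
    sum(Reduce(`&`, lapply(ex$sessions, `[[`, "active_mask")))
  }, numeric(1))
  expect_lt(abs(mean(counts) - 100 * 0.8^13), 4)

  ex1 <- generate_experiment(n_cells = 20, n_sessions = 3, n_trials = 2,
                             active_prob = 1, seed = 1)
  expect_true(all(vapply(ex1$sessions, function(s) all(s$active_mask),
                         logical(1))))
})

test_that("session containers round-trip through the text format", {
  fx <- fix_two_days()
  ses <- fx$ground_truth
  raw <- generate_experiment(n_cells = 4, n_sessions = 1, n_trials = 4,
                             seed = 77)$sessions[[1]]
  path <- file.path(tempdir(), "ses_roundtrip")
  write_session(raw, path)
  back <- read_session(path)
  expect_equal(back$traces, raw$traces, ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(back$trials$choice, raw$trials$choice)
  expect_equal(back$centroids, raw$centroids, ignore_attr = TRUE)
  expect_equal(attr(back$track, "frame_rate"), attr(raw$track, "frame_rate"))
  gt_path <- file.path(tempdir(), "gt.json")
  write_ground_truth(fx$ground_truth, gt_path)
  gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
  expect_equal(gt$days, fx$ground_truth$days)
  unlink(path, recursive = TRUE); unlink(gt_path)
})
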