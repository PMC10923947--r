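# Shared fixtures, built once per test run and cached.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small drift-free two-day experiment, preprocessed.
fix_two_days <- function() cached("two_days", function() {
  ex <- generate_experiment(n_cells = 25, n_sessions = 2, n_trials = 24,
                            trace_noise_sd = 0.1, seed = 42)
  list(sessions = lapply(ex$sessions, preprocess_session),
       ground_truth = ex$ground_truth)
})

# One behavioral session (no traces), reused for map/decoder tests.
fix_behavior <- function() cached("behavior", function()
  simulate_maze_trajectories(n_trials = 24, seed = 7))

# Crafted linearized runs on a uniform position grid: n_per_dir runs per
# direction, each visiting every position in (0, 1] exactly once, with a
# configurable x-profile. `frames` index into a virtual trace of length
# n_runs * n_pos.
make_grid_runs <- function(n_per_dir = 4, n_pos = 100,
                           x_fun = function(u, dir) 0) {
  runs <- list()
  frame0 <- 0L
  for (i in seq_len(2 * n_per_dir)) {
    dir <- if (i %% 2 == 1) "left" else "right"
    u <- (seq_len(n_pos) - 0.5) / n_pos
    runs[[i]] <- list(trial = i, direction = dir,
                      frames = frame0 + seq_len(n_pos),
                      u = u, x = x_fun(u, dir))
    frame0 <- frame0 + n_pos
  }
  runs
}

# Independent angle oracle: brute-force pairwise edge angles at each corner.
oracle_edge_angles <- function(pv) {
  A <- matrix(NA_real_, 6, 10)
  for (c0 in 1:6) {
    others <- setdiff(1:6, c0)
    k <- 0
    for (a in 1:4) for (b in (a + 1):5) {
      k <- k + 1
      e1 <- pv[, others[a]] - pv[, c0]
      e2 <- pv[, others[b]] - pv[, c0]
      A[c0, k] <- acos(min(max(sum(e1 * e2) /
                                 sqrt(sum(e1^2) * sum(e2^2)), -1), 1))
    }
  }
  A
}
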