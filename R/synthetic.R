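#' Maze geometry for the two-choice M-maze
#'
#' Describes the outward path (sampling port -> center arm -> side arm ->
#' reward) as lengths of the three corridor pieces. The divergence of left
#' and right trajectories sits at the end of the center arm, i.e. at linear
#' position `center / (center + top + side)`.
#'
#' @param center length of the shared center arm (cm).
#' @param top length of the top corridor from the center-arm exit to the
#'   side arm (cm).
#' @param side length of the descending side arm to the reward site (cm).
#' @return an object of class `maze_geometry`.
#' @export
maze_geometry <- function(center = 40, top = 40, side = 30) {
  stopifnot(center > 0, top > 0, side > 0)
  structure(list(center = center, top = top, side = side,
                 total = center + top + side),
            class = "maze_geometry")
}

#' Four-segment skeleton of one outward trajectory
#'
#' The 2D path of an outward run approximated as 4 connected line segments,
#' used both to lay out synthetic trajectories and to linearize tracked
#' positions.
#'
#' @param geometry a [maze_geometry()].
#' @param direction `"left"` or `"right"`.
#' @return object of class `maze_skeleton`: matrix of 5 vertices (x, y) and
#'   cumulative arc length.
#' @export
maze_skeleton <- function(geometry = maze_geometry(), direction = c("left", "right")) {
  direction <- match.arg(direction)
  s <- if (direction == "left") -1 else 1
  g <- geometry
  v <- rbind(c(0, 0),
             c(0, g$center),
             c(s * g$top / 2, g$center),
             c(s * g$top, g$center),
             c(s * g$top, g$center - g$side))
  seg <- diff(v)
  len <- sqrt(rowSums(seg^2))
  if (any(len <= 0)) stop("degenerate maze skeleton: zero-length segment")
  structure(list(vertices = v, seg_len = len, cum_len = c(0, cumsum(len)),
                 total = sum(len), direction = direction),
            class = "maze_skeleton")
}

# Point on a skeleton at normalized arc length u in [0, 1].
skeleton_point <- function(skel, u) {
  d <- pmin(pmax(u, 0), 1) * skel$total
  seg <- findInterval(d, skel$cum_len, rightmost.closed = TRUE)
  seg[seg > length(skel$seg_len)] <- length(skel$seg_len)
  frac <- (d - skel$cum_len[seg]) / skel$seg_len[seg]
  p0 <- skel$vertices[seg, , drop = FALSE]
  p1 <- skel$vertices[seg + 1L, , drop = FALSE]
  p0 + (p1 - p0) * frac
}

#' Simulate maze trajectories for one session
#'
#' Generates a 20 Hz behavioral track and trial table for an M-maze session:
#' per trial a sampling epoch at the odor port, a smooth outward run through
#' the center arm to one side arm's reward site, and a reward epoch. Left and
#' right runs share the center-arm corridor up to the maze's divergence
#' location. Sessions hold ~40 trials by default, mirroring a 15-minute
#' recording.
#'
#' @param n_trials number of trials (>= 2).
#' @param p_left probability that a trial's correct target is the left arm.
#' @param p_error probability that the animal chooses the wrong arm.
#' @param frame_rate sampling rate, Hz.
#' @param geometry a [maze_geometry()].
#' @param run_duration mean outward-run duration, s.
#' @param samp_frames,reward_frames frames spent at the odor port / reward site.
#' @param pos_noise_sd lateral tracking noise, cm.
#' @param speed_jitter log-sd of per-frame speed multipliers (trajectory
#'   smoothness).
#' @param seed RNG seed (mandatory).
#' @return list with elements `track` (data.frame `t`, `x`, `y` plus
#'   ground-truth columns `u_true`, `dir_true` that analysis code must not
#'   use) and `trials` (data.frame, one row per trial with frame bounds,
#'   epoch boundaries, cue, choice and correctness).
#' @export
simulate_maze_trajectories <- function(n_trials = 40, p_left = 0.5,
                                       p_error = 0, frame_rate = 20,
                                       geometry = maze_geometry(),
                                       run_duration = 4,
                                       samp_frames = 20, reward_frames = 20,
                                       pos_noise_sd = 0.5,
                                       speed_jitter = 0.3,
                                       seed) {
  if (n_trials < 2) stop("n_trials must be >= 2")
  stopifnot(p_left >= 0, p_left <= 1, frame_rate > 0, run_duration > 0)
  if (missing(seed)) stop("seed is a mandatory argument")
  with_seed(seed, {
    skel <- list(left = maze_skeleton(geometry, "left"),
                 right = maze_skeleton(geometry, "right"))
    div_frac <- geometry$center / geometry$total

    cue <- ifelse(stats::runif(n_trials) < p_left, "left", "right")
    err <- stats::runif(n_trials) < p_error
    choice <- ifelse(err, ifelse(cue == "left", "right", "left"), cue)

    xs <- ys <- us <- numeric(0)
    dirs <- character(0)
    rows <- vector("list", n_trials)
    frame0 <- 0L
    for (i in seq_len(n_trials)) {
      n_run <- max(10L, round(frame_rate * run_duration *
                                exp(stats::rnorm(1, 0, 0.1))))
      # monotone progress along the path with jittered per-frame speed
      w <- exp(stats::rnorm(n_run, 0, speed_jitter))
      u <- cumsum(w) / sum(w)
      sk <- skel[[choice[i]]]
      p_run <- skeleton_point(sk, u)
      port <- matrix(rep(c(0, -3), each = samp_frames), ncol = 2)
      rew <- matrix(rep(sk$vertices[5, ], each = reward_frames), ncol = 2)
      p <- rbind(port, p_run, rew)
      p <- p + matrix(stats::rnorm(length(p), 0, pos_noise_sd), ncol = 2)
      n_tot <- nrow(p)
      u_all <- c(rep(NA_real_, samp_frames), u, rep(NA_real_, reward_frames))
      d_all <- c(rep(NA_character_, samp_frames),
                 rep(choice[i], n_run), rep(NA_character_, reward_frames))

      run_start <- frame0 + samp_frames + 1L
      div_idx <- which(u >= div_frac)[1]
      rows[[i]] <- data.frame(
        trial = i,
        start_frame = frame0 + 1L,
        end_frame = frame0 + n_tot,
        cue = cue[i], choice = choice[i], correct = !err[i],
        samp_end = frame0 + samp_frames,
        run_start = run_start,
        center_end = run_start + div_idx - 2L,
        run_end = frame0 + samp_frames + n_run,
        stringsAsFactors = FALSE)
      xs <- c(xs, p[, 1]); ys <- c(ys, p[, 2])
      us <- c(us, u_all); dirs <- c(dirs, d_all)
      frame0 <- frame0 + n_tot
    }
    trials <- do.call(rbind, rows)
    track <- data.frame(t = (seq_len(frame0) - 1) / frame_rate,
                        x = xs, y = ys, u_true = us, dir_true = dirs,
                        stringsAsFactors = FALSE)
    attr(track, "frame_rate") <- frame_rate
    attr(track, "geometry") <- geometry
    list(track = track, trials = trials)
  })
}

#' Ground-truth cell population
#'
#' Draws a population of model neurons with place-field-like tuning on the
#' linearized outward trajectory, side preference, speed- and goal-modulation
#' and per-day detection probability. `direction_bias` controls how strongly
#' left/right gains are skewed: 0 gives equal gains (expected side index 0),
#' 1 gives fully one-sided cells.
#'
#' @param n number of cells.
#' @param amplitude transient amplitude (z-units once divided by trace noise).
#' @param field_width sd of the tuning bump, linear-position units.
#' @param direction_bias in \[0, 1\]; fraction of maximal side asymmetry
#'   (drawn per cell as `runif(0, direction_bias)` toward a random side).
#' @param p_distinct_fields probability that a cell's right-trajectory
#'   field center is independent of its left one (trajectory-specific
#'   tuning); the remaining cells share one field across directions.
#' @param speed_mod,goal_mod multiplicative modulation depth of speed quartile
#'   and goal factors (0 = none).
#' @param active_prob per-day probability a cell is detected as active.
#' @param prop_tuned fraction of cells with spatial tuning; the rest fire
#'   uniformly along the track.
#' @param seed RNG seed.
#' @return data.frame of class `ground_truth_cells`.
#' @export
ground_truth_cells <- function(n, amplitude = 1.5, field_width = 0.08,
                               direction_bias = 0.6,
                               p_distinct_fields = 0.5, speed_mod = 0,
                               goal_mod = 0, active_prob = 1,
                               prop_tuned = 1, seed) {
  stopifnot(n >= 1, active_prob >= 0, active_prob <= 1,
            direction_bias >= 0, direction_bias <= 1)
  if (missing(seed)) stop("seed is a mandatory argument")
  with_seed(seed, {
    bias <- stats::runif(n, 0, direction_bias) *
      sample(c(-1, 1), n, replace = TRUE)
    # somata are spatially exclusive: a jittered square grid keeps cell
    # bodies apart like packed somata in a field of view, at any n
    side <- ceiling(sqrt(n))
    spacing <- 180 / side
    grid_xy <- expand.grid(x = 10 + (seq_len(side) - 0.5) * spacing,
                           y = 10 + (seq_len(side) - 0.5) * spacing)
    slots <- sample(nrow(grid_xy), n)
    fov <- as.matrix(grid_xy[slots, ]) +
      matrix(stats::runif(2 * n, -spacing / 4, spacing / 4), n, 2)
    sq <- matrix(1 + speed_mod * stats::runif(n * 4, -1, 1), nrow = n)
    gq <- matrix(1 + goal_mod * stats::runif(n * 2, -1, 1), nrow = n)
    center_l <- stats::runif(n)
    center_r <- ifelse(stats::runif(n) < p_distinct_fields,
                       stats::runif(n), center_l)
    cells <- data.frame(
      cell = seq_len(n),
      field_center = center_l,
      field_center_right = center_r,
      field_width = rep(field_width, n),
      amplitude = rep(amplitude, n),
      gain_left = pmax(0, 1 + bias),
      gain_right = pmax(0, 1 - bias),
      tuned = stats::runif(n) < prop_tuned,
      speed_q1 = sq[, 1], speed_q2 = sq[, 2],
      speed_q3 = sq[, 3], speed_q4 = sq[, 4],
      goal_left = gq[, 1], goal_right = gq[, 2],
      active_prob = rep(active_prob, n),
      fov_x = fov[, 1],
      fov_y = fov[, 2],
      blob_sx = stats::runif(n, 5.5, 7.5),
      blob_sy = stats::runif(n, 5.5, 7.5),
      blob_theta = stats::runif(n, 0, pi))
    class(cells) <- c("ground_truth_cells", "data.frame")
    cells
  })
}

#' Drift configuration
#'
#' Parameters of the cross-day drift model: per session (or per elapsed day)
#' each cell's tuning circularly shifts by 1 bin of the 20-bin outward grid
#' with probability `p_drift`; once the cumulative shift exceeds
#' `regularization_limit` bins, subsequent steps are random -1/+1 so the
#' field cannot wrap back onto its origin. `noise_sd` is the sd of additive
#' per-bin tuning noise (0 to 0.5).
#'
#' @param p_drift per-step shift probability, in \[0, 1\].
#' @param noise_sd additive tuning-noise sd, >= 0.
#' @param n_sessions number of sessions the configuration spans.
#' @param regularization_limit cumulative-shift limit, bins.
#' @param per_day if `TRUE`, one drift step per elapsed calendar day rather
#'   than per session.
#' @export
drift_config <- function(p_drift = 0, noise_sd = 0, n_sessions = 2,
                         regularization_limit = 10, per_day = FALSE) {
  stopifnot(p_drift >= 0, p_drift <= 1, noise_sd >= 0, n_sessions >= 1)
  structure(list(p_drift = p_drift, noise_sd = noise_sd,
                 n_sessions = n_sessions,
                 regularization_limit = regularization_limit,
                 per_day = per_day),
            class = "drift_config")
}

# One drift step applied to a vector of cumulative shifts (bins).
# `dirs` is each cell's habitual drift direction (+1/-1).
drift_step <- function(cum, dirs, p_drift, limit) {
  n <- length(cum)
  move <- stats::runif(n) < p_drift
  step <- dirs
  over <- abs(cum) > limit
  if (any(over)) step[over] <- sample(c(-1, 1), sum(over), replace = TRUE)
  cum + ifelse(move, step, 0)
}

#' Cross-day drift states for a cell population
#'
#' @param cells a [ground_truth_cells()] table.
#' @param config a [drift_config()].
#' @param days optional calendar day of each session (length
#'   `config$n_sessions`); with `config$per_day = TRUE` one drift step is
#'   taken per elapsed day between sessions.
#' @param seed RNG seed.
#' @return integer matrix cells x sessions of cumulative field shifts in
#'   bins of the 20-bin grid (first session all zero).
#' @export
apply_cross_day_drift <- function(cells, config, days = NULL, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  n <- nrow(cells)
  ns <- config$n_sessions
  steps_between <- if (config$per_day && !is.null(days)) diff(days)
                   else rep(1L, ns - 1L)
  with_seed(seed, {
    dirs <- rep(1, n)
    shifts <- matrix(0L, nrow = n, ncol = ns)
    if (ns > 1) {
      for (s in 2:ns) {
        cum <- shifts[, s - 1L]
        for (k in seq_len(steps_between[s - 1L]))
          cum <- drift_step(cum, dirs, config$p_drift,
                            config$regularization_limit)
        shifts[, s] <- as.integer(cum)
      }
    }
    shifts
  })
}

# Tuning bump: circular Gaussian on linearized position in [0,1].
circular_bump <- function(u, center, width) {
  d <- abs(u - center)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / width)^2)
}

# Single-exponential calcium-indicator kernel (GCaMP6f-like), tau seconds,
# with a 2-frame linear rise so transients have a resolvable rising phase.
calcium_kernel <- function(frame_rate, tau = 0.7) {
  n <- ceiling(5 * tau * frame_rate)
  decay <- exp(-(0:n) / (tau * frame_rate))
  c(0.5, decay)
}

#' Synthesize one session of calcium traces
#'
#' Forward model: per-frame event rate = amplitude x circular tuning bump at
#' the (drift-shifted) field center x direction gain x speed-quartile gain x
#' goal gain, with optional additive per-bin tuning noise for the day. Events
#' are drawn as Bernoulli per frame, convolved with a decaying indicator
#' kernel, and the trace receives a baseline offset, a slow sinusoidal
#' baseline drift and white noise, so that the preprocessing stages (baseline
#' filtering, iterative z-scoring, transient detection) all have work to do.
#'
#' @param cells a [ground_truth_cells()] table.
#' @param behavior output of [simulate_maze_trajectories()].
#' @param drift_shift integer vector of per-cell cumulative field shifts in
#'   20-bin units for this day (default 0).
#' @param tuning_noise_sd sd of the day's additive per-bin tuning noise.
#' @param trace_noise_sd white-noise sd of the raw trace (must be >= 0).
#' @param event_rate peak event rate at the field center, Hz.
#' @param slow_drift_amplitude amplitude of the slow sinusoidal baseline
#'   drift of the raw trace (arbitrary units; period ~4 min).
#' @param day_index integer day label.
#' @param footprint_jitter_sd sd (pixels) of the day's footprint centroid
#'   jitter, for registration tests.
#' @param seed RNG seed.
#' @return object of class `calcium_session`: raw `traces` (cells x frames),
#'   `track`, `trials`, `day_index`, per-cell `centroids` and footprint
#'   shape parameters, and `active_mask`.
#' @export
synthesize_session <- function(cells, behavior, drift_shift = NULL,
                               tuning_noise_sd = 0, trace_noise_sd = 0.1,
                               event_rate = 2.5,
                               slow_drift_amplitude = 0.5, day_index = 1L,
                               footprint_jitter_sd = 0, seed) {
  if (trace_noise_sd < 0) stop("trace_noise_sd must be >= 0")
  if (tuning_noise_sd < 0) stop("tuning_noise_sd must be >= 0")
  if (missing(seed)) stop("seed is a mandatory argument")
  track <- behavior$track
  trials <- behavior$trials
  fr <- attr(track, "frame_rate")
  n_frames <- nrow(track)
  n_cells <- nrow(cells)
  if (is.null(drift_shift)) drift_shift <- rep(0L, n_cells)
  stopifnot(length(drift_shift) == n_cells)

  u <- track$u_true
  dirs <- track$dir_true
  run <- !is.na(u)
  # per-frame speed on run frames, quartile-coded within the session
  dx <- c(0, diff(track$x)); dy <- c(0, diff(track$y))
  speed <- sqrt(dx^2 + dy^2) * fr
  sq <- rep(1L, n_frames)
  if (any(run)) {
    qs <- stats::quantile(speed[run], c(0.25, 0.5, 0.75))
    sq[run] <- 1L + findInterval(speed[run], qs)
  }
  goal <- ifelse(dirs == "left", 1L, 2L)

  with_seed(seed, {
    kern <- calcium_kernel(fr)
    bins <- rep(NA_integer_, n_frames)
    bins[run] <- position_bin(u[run], 20L)
    left_fr <- run & !is.na(dirs) & dirs == "left"
    right_fr <- run & !is.na(dirs) & dirs == "right"
    events <- matrix(0, nrow = n_frames, ncol = n_cells)
    for (ci in seq_len(n_cells)) {
      cl <- cells[ci, ]
      center_r <- if (is.null(cl$field_center_right)) cl$field_center
                  else cl$field_center_right
      ctr_l <- (cl$field_center + drift_shift[ci] / 20) %% 1
      ctr_r <- (center_r + drift_shift[ci] / 20) %% 1
      bump <- rep(0, n_frames)
      if (isTRUE(cl$tuned)) {
        bump[left_fr] <- circular_bump(u[left_fr], ctr_l, cl$field_width)
        bump[right_fr] <- circular_bump(u[right_fr], ctr_r, cl$field_width)
      } else {
        bump[run] <- 0.4
      }
      if (tuning_noise_sd > 0) {
        pert <- stats::rnorm(20, 0, tuning_noise_sd)
        bump[run] <- pmax(0, bump[run] + pert[bins[run]])
      }
      dir_gain <- rep(0, n_frames)
      dir_gain[run] <- ifelse(dirs[run] == "left", cl$gain_left, cl$gain_right)
      spd_gain <- c(cl$speed_q1, cl$speed_q2, cl$speed_q3, cl$speed_q4)[sq]
      goal_gain <- rep(1, n_frames)
      goal_gain[run] <- c(cl$goal_left, cl$goal_right)[goal[run]]
      rate <- event_rate * bump * dir_gain * spd_gain * goal_gain
      p_event <- pmin(1, rate / fr)
      events[, ci] <- (stats::runif(n_frames) < p_event) * cl$amplitude
    }
    # causal convolution with the indicator kernel, batched over cells
    npad <- stats::nextn(n_frames + length(kern))
    E <- rbind(events, matrix(0, npad - n_frames, n_cells))
    fk <- stats::fft(c(kern, numeric(npad - length(kern))))
    S <- Re(stats::mvfft(stats::mvfft(E) * fk, inverse = TRUE)) / npad
    phases <- stats::runif(n_cells, 0, 2 * pi)
    slow <- slow_drift_amplitude *
      sin(outer(2 * pi * track$t / 240, phases, `+`))
    noise <- if (trace_noise_sd > 0)
      matrix(stats::rnorm(n_frames * n_cells, 0, trace_noise_sd),
             n_frames, n_cells) else 0
    traces <- t(5 + slow + S[seq_len(n_frames), , drop = FALSE] + noise)
    active <- stats::runif(n_cells) < cells$active_prob
    centroids <- cbind(
      x = cells$fov_x + stats::rnorm(n_cells, 0, footprint_jitter_sd),
      y = cells$fov_y + stats::rnorm(n_cells, 0, footprint_jitter_sd))
    structure(list(traces = traces, track = track, trials = trials,
                   day_index = as.integer(day_index),
                   centroids = centroids,
                   footprint_pars = cells[, c("blob_sx", "blob_sy",
                                              "blob_theta")],
                   active_mask = active),
              class = "calcium_session")
  })
}

#' @export
print.calcium_session <- function(x, ...) {
  cat(sprintf("<calcium_session> day %d: %d cells x %d frames, %d trials (%d correct)\n",
              x$day_index, nrow(x$traces), ncol(x$traces),
              nrow(x$trials), sum(x$trials$correct)))
  invisible(x)
}

#' Generate a multi-day synthetic experiment
#'
#' Orchestrates cells, behavior, drift and dropout into a list of daily
#' sessions plus a ground-truth sidecar enabling parameter-recovery tests.
#' The default design mirrors a multi-week longitudinal recording: 13
#' sessions spanning 24 calendar days, ~40 trials each.
#'
#' @param n_cells population size.
#' @param n_sessions number of recording sessions.
#' @param days calendar day of each session (strictly increasing).
#' @param n_trials trials per session.
#' @param drift a [drift_config()].
#' @param cells optional pre-built [ground_truth_cells()]; default drawn here.
#' @param active_prob per-day activity probability (used when `cells` is
#'   built here).
#' @param trace_noise_sd raw-trace white-noise sd.
#' @param slow_drift_amplitude slow baseline-drift amplitude of raw traces.
#' @param footprint_jitter_sd per-day footprint centroid jitter, px.
#' @param p_left,p_error,direction_bias,p_distinct_fields,speed_mod,
#'   goal_mod,prop_tuned passed through to the behavior and cell
#'   generators.
#' @param seed master seed; all per-day seeds derive from it.
#' @return list with `sessions` (list of `calcium_session`) and
#'   `ground_truth` (cells, drift-shift matrix, configuration echo).
#' @export
generate_experiment <- function(n_cells = 100, n_sessions = 13,
                                days = NULL, n_trials = 40,
                                drift = drift_config(n_sessions = n_sessions),
                                cells = NULL, active_prob = 1,
                                trace_noise_sd = 0.1,
                                slow_drift_amplitude = 0.5,
                                footprint_jitter_sd = 0,
                                p_left = 0.5, p_error = 0,
                                direction_bias = 0.6,
                                p_distinct_fields = 0.5, speed_mod = 0,
                                goal_mod = 0, prop_tuned = 1,
                                seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  if (is.null(days)) {
    # 13 sessions over 24 nominal days: near-evenly spaced
    days <- round(seq(1, 1 + (n_sessions - 1) * 23 / 12))[seq_len(n_sessions)]
    if (n_sessions == 13) days <- round(seq(1, 24, length.out = 13))
  }
  stopifnot(length(days) == n_sessions, all(diff(days) > 0))
  drift$n_sessions <- n_sessions
  if (is.null(cells))
    cells <- ground_truth_cells(n_cells, active_prob = active_prob,
                                direction_bias = direction_bias,
                                p_distinct_fields = p_distinct_fields,
                                speed_mod = speed_mod, goal_mod = goal_mod,
                                prop_tuned = prop_tuned,
                                seed = child_seed(seed, 1))
  shifts <- apply_cross_day_drift(cells, drift, days = days,
                                  seed = child_seed(seed, 2))
  sessions <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    beh <- simulate_maze_trajectories(n_trials = n_trials, p_left = p_left,
                                      p_error = p_error,
                                      seed = child_seed(seed, 10 + s))
    sessions[[s]] <- synthesize_session(
      cells, beh, drift_shift = shifts[, s],
      tuning_noise_sd = drift$noise_sd,
      trace_noise_sd = trace_noise_sd,
      slow_drift_amplitude = slow_drift_amplitude,
      day_index = days[s],
      footprint_jitter_sd = footprint_jitter_sd,
      seed = child_seed(seed, 100 + s))
  }
  list(sessions = sessions,
       ground_truth = list(cells = cells, drift_bins = shifts,
                           days = days, drift = drift, seed = seed))
}
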