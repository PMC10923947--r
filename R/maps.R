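#' Linearize tracked positions onto a maze skeleton
#'
#' Projects each x/y sample onto its nearest point of the 4-segment skeleton
#' and returns the normalized arc length in \[0, 1\] (0 = center-arm entry,
#' 1 = side-arm end). Points equidistant from two segments resolve to the
#' lower segment index.
#'
#' @param x,y coordinates (cm).
#' @param skeleton a [maze_skeleton()].
#' @return numeric vector of linear positions.
#' @export
linearize <- function(x, y, skeleton) {
  n <- length(x)
  if (n == 0L) stop("empty track")
  stopifnot(length(y) == n)
  v <- skeleton$vertices
  nseg <- nrow(v) - 1L
  best_d2 <- rep(Inf, n)
  best_arc <- rep(NA_real_, n)
  for (s in seq_len(nseg)) {
    a <- v[s, ]; b <- v[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    tt <- pmin(pmax(((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2, 0), 1)
    px <- a[1] + tt * ab[1]; py <- a[2] + tt * ab[2]
    d2 <- (x - px)^2 + (y - py)^2
    upd <- d2 < best_d2          # strict: ties keep the lower segment index
    best_arc[upd] <- skeleton$cum_len[s] + tt[upd] * skeleton$seg_len[s]
    best_d2[upd] <- d2[upd]
  }
  best_arc / skeleton$total
}

#' Segment a session into linearized outward runs
#'
#' Extracts one outward run (sampling port to reward site) per correct
#' trial, linearized with the skeleton of the chosen side. Incorrect trials
#' are dropped.
#'
#' @param track behavioral track (data.frame with `x`, `y`; geometry in
#'   `attr(track, "geometry")` unless given).
#' @param trials trial table with `run_start`, `run_end`, `choice`,
#'   `correct`.
#' @param geometry a [maze_geometry()].
#' @return list of runs; each run is a list with `trial`, `direction`,
#'   `frames` (global frame indices), `u` (linear position) and `x`.
#' @export
segment_runs <- function(track, trials, geometry = attr(track, "geometry")) {
  if (is.null(geometry)) stop("no maze geometry available")
  skels <- list(left = maze_skeleton(geometry, "left"),
                right = maze_skeleton(geometry, "right"))
  runs <- list()
  for (i in seq_len(nrow(trials))) {
    if (!trials$correct[i]) next
    fr <- trials$run_start[i]:trials$run_end[i]
    dir <- trials$choice[i]
    u <- linearize(track$x[fr], track$y[fr], skels[[dir]])
    runs[[length(runs) + 1L]] <- list(trial = trials$trial[i],
                                      direction = dir, frames = fr,
                                      u = u, x = track$x[fr])
  }
  runs
}

run_directions <- function(runs) vapply(runs, `[[`, character(1), "direction")

#' Trajectory divergence point of left and right runs
#'
#' Interpolates each run's linear position and x-coordinate by a factor of
#' 10, bins x as a function of linear position (50 bins), and compares left
#' versus right x per bin with an independent two-sample t-test, Bonferroni
#' corrected for the 50 comparisons. The first significant bin is the
#' divergence point.
#'
#' @param runs output of [segment_runs()]; needs >= 2 runs per direction.
#' @param n_bins number of linear-position bins.
#' @param alpha family-wise significance level.
#' @return list with `bin` (first significant bin, `NA` when no bin is
#'   significant), `position` (bin center in \[0, 1\]) and the per-bin
#'   corrected `p_values`.
#' @export
divergence_point <- function(runs, n_bins = 50, alpha = 0.05) {
  dirs <- run_directions(runs)
  if (sum(dirs == "left") < 2 || sum(dirs == "right") < 2)
    stop("divergence detection needs >= 2 runs per direction")
  # per run: mean x in each linear-position bin, after 10x interpolation
  binned <- lapply(runs, function(r) {
    n <- length(r$u)
    grid <- seq(1, n, length.out = 10L * n)
    ui <- stats::approx(seq_len(n), r$u, grid)$y
    xi <- stats::approx(seq_len(n), r$x, grid)$y
    b <- position_bin(ui, n_bins)
    out <- rep(NA_real_, n_bins)
    m <- tapply(xi, b, mean)
    out[as.integer(names(m))] <- m
    out
  })
  xmat <- do.call(rbind, binned)
  p <- rep(NA_real_, n_bins)
  for (b in seq_len(n_bins)) {
    xl <- xmat[dirs == "left", b]; xr <- xmat[dirs == "right", b]
    xl <- xl[is.finite(xl)]; xr <- xr[is.finite(xr)]
    if (length(xl) < 2 || length(xr) < 2) next
    if (stats::sd(c(xl, xr)) == 0) { p[b] <- 1; next }
    p[b] <- tryCatch(stats::t.test(xl, xr, var.equal = TRUE)$p.value,
                     error = function(e) NA_real_)
  }
  p_adj <- pmin(p * n_bins, 1)
  sig <- which(is.finite(p_adj) & p_adj < alpha)
  bin <- if (length(sig)) sig[1] else NA_integer_
  list(bin = bin,
       position = if (is.na(bin)) NA_real_ else (bin - 0.5) / n_bins,
       p_values = p_adj)
}

#' Trajectory-specific spatial tuning function
#'
#' Bins a neuron's activity as a function of linearized position over all
#' runs of one direction (20 bins covering the outward trajectory), divides
#' the binned signal by the bins' occupation probability and normalizes to
#' the bin with the largest mean activity. Unvisited bins get occupancy 0
#' and `NA` values; an all-zero map is returned unnormalized and flagged.
#'
#' @param activity per-frame activity for the neuron (full-session vector:
#'   z-scored trace, transient signal or rising-phase signal).
#' @param runs output of [segment_runs()].
#' @param direction `"left"` or `"right"`.
#' @param n_bins number of spatial bins.
#' @return list of class `tuning_function`: `values` (peak-normalized),
#'   `raw_rate` (mean activity per bin), `occupancy` (probabilities summing
#'   to 1 over visited bins), `direction`, `n_runs`, `all_zero`.
#' @export
tuning_function <- function(activity, runs, direction, n_bins = 20) {
  sel <- runs[run_directions(runs) == direction]
  if (length(sel) == 0L) stop("no runs of direction '", direction, "'")
  u <- unlist(lapply(sel, `[[`, "u"))
  fr <- unlist(lapply(sel, `[[`, "frames"))
  a <- activity[fr]
  b <- position_bin(u, n_bins)
  cnt <- tabulate(b, n_bins)
  s <- rep(0, n_bins)
  agg <- tapply(a, b, sum)
  s[as.integer(names(agg))] <- agg
  occ <- cnt / sum(cnt)
  raw <- ifelse(cnt > 0, s / cnt, NA_real_)
  val <- ifelse(cnt > 0, s / occ, NA_real_)
  all_zero <- all(!is.finite(val) | val == 0)
  if (!all_zero) val <- val / max(val, na.rm = TRUE)
  structure(list(values = val, raw_rate = raw, occupancy = occ,
                 direction = direction, n_runs = length(sel),
                 all_zero = all_zero),
            class = "tuning_function")
}

#' Side index
#'
#' Normalized left/right asymmetry of transient activity,
#' `S = (a_l - a_r) / (a_l + a_r)`, ranging from -1 (right-only, with the
#' convention that `a_l` comes first) to 1 (left-only).
#'
#' @param a_l,a_r mean transient activity during left / right trajectories
#'   (non-negative).
#' @return S in \[-1, 1\]; `NA` when both activities are 0.
#' @export
side_index <- function(a_l, a_r) {
  stopifnot(all(a_l >= 0), all(a_r >= 0))
  s <- a_l + a_r
  ifelse(s == 0, NA_real_, (a_l - a_r) / s)
}

#' Spatial information of a rate map
#'
#' `SI = sum_i lambda_i * ln(lambda_i / lambda) * p_i`, where `lambda_i` is
#' the mean transient activity in bin i, `p_i` the bin's occupation
#' probability and `lambda = sum_i p_i * lambda_i` the occupancy-weighted
#' mean activity across the trajectory. Bins with zero rate contribute 0
#' (`0 * ln 0 := 0`).
#'
#' @param rate per-bin mean activity `lambda_i` (`NA` for unvisited bins).
#' @param occupancy per-bin occupation probabilities summing to 1.
#' @return scalar SI; 0 with a warning when the map is all-zero.
#' @export
spatial_information <- function(rate, occupancy) {
  stopifnot(length(rate) == length(occupancy))
  ok <- is.finite(rate) & occupancy > 0
  lam <- sum(rate[ok] * occupancy[ok])
  if (lam <= 0) {
    warning("all-zero rate map: SI undefined, returning 0")
    return(0)
  }
  pos <- ok & rate > 0
  sum(rate[pos] * log(rate[pos] / lam) * occupancy[pos])
}

# Logical frame mask for a behavioral epoch over correct trials.
# "center": run frames up to the divergence of trajectories;
# "side": run frames after it; "run": the whole outward run.
epoch_mask <- function(session, epoch = c("center", "side", "run",
                                          "sampling", "reward"),
                       correct_only = TRUE) {
  epoch <- match.arg(epoch)
  n <- ncol(session$traces)
  mask <- rep(FALSE, n)
  tr <- session$trials
  for (i in seq_len(nrow(tr))) {
    if (correct_only && !tr$correct[i]) next
    idx <- switch(epoch,
      sampling = tr$start_frame[i]:tr$samp_end[i],
      center = tr$run_start[i]:tr$center_end[i],
      side = (tr$center_end[i] + 1L):tr$run_end[i],
      run = tr$run_start[i]:tr$run_end[i],
      reward = (tr$run_end[i] + 1L):tr$end_frame[i])
    mask[idx] <- TRUE
  }
  mask
}

# Frame mask restricted to trials of one chosen side.
epoch_mask_direction <- function(session, direction, epoch = "run",
                                 correct_only = TRUE) {
  n <- ncol(session$traces)
  mask <- rep(FALSE, n)
  tr <- session$trials
  for (i in seq_len(nrow(tr))) {
    if (correct_only && !tr$correct[i]) next
    if (tr$choice[i] != direction) next
    idx <- switch(epoch,
      center = tr$run_start[i]:tr$center_end[i],
      side = (tr$center_end[i] + 1L):tr$run_end[i],
      run = tr$run_start[i]:tr$run_end[i])
    mask[idx] <- TRUE
  }
  mask
}

#' Tuning functions for all neurons of a preprocessed session
#'
#' @param session a [preprocess_session()] output.
#' @param activity which activity representation feeds the maps:
#'   z-scored traces (default, used for tuning correlations), the
#'   transient-masked signal (used for SI and side index) or rising phases.
#' @param parity `"all"`, `"odd"` or `"even"` runs.
#' @param n_bins spatial bins.
#' @return list with per-direction elements; each holds `values` and `raw`
#'   (cells x bins matrices), `occupancy`, and `n_runs`.
#' @export
session_tuning <- function(session, activity = c("z", "transients", "rising"),
                           parity = c("all", "odd", "even"), n_bins = 20) {
  activity <- match.arg(activity)
  parity <- match.arg(parity)
  act <- switch(activity, z = session$z, transients = session$transient_signal,
                rising = session$rising)
  if (is.null(act)) stop("session not preprocessed; run preprocess_session()")
  runs <- segment_runs(session$track, session$trials)
  out <- list()
  for (dir in c("left", "right")) {
    dr <- runs[run_directions(runs) == dir]
    if (parity != "all") {
      idx <- seq_along(dr)
      keep <- if (parity == "odd") idx %% 2L == 1L else idx %% 2L == 0L
      dr <- dr[keep]
    }
    if (length(dr) == 0L) {
      out[[dir]] <- NULL
      next
    }
    vals <- raw <- matrix(NA_real_, nrow(act), n_bins)
    occ <- NULL
    for (ci in seq_len(nrow(act))) {
      tf <- tuning_function(act[ci, ], dr, dir, n_bins)
      vals[ci, ] <- tf$values
      raw[ci, ] <- tf$raw_rate
      occ <- tf$occupancy
    }
    out[[dir]] <- list(values = vals, raw = raw, occupancy = occ,
                       n_runs = length(dr))
  }
  out
}

#' Per-neuron side index and spatial information for a session
#'
#' Side index uses mean transient activity over the outward runs of each
#' direction; SI uses transient activity binned on the 20-bin grid,
#' separately per direction.
#'
#' @param session a preprocessed session.
#' @param epoch epoch for the side-index activity (default whole outward
#'   run; `"center"` restricts to center-arm travel).
#' @return data.frame with `cell`, `side_index`, `si_left`, `si_right`,
#'   `a_left`, `a_right`.
#' @export
session_cell_stats <- function(session, epoch = "run") {
  if (is.null(session$z)) stop("session not preprocessed")
  n_cells <- nrow(session$z)
  ml <- epoch_mask_direction(session, "left", epoch)
  mr <- epoch_mask_direction(session, "right", epoch)
  tun <- session_tuning(session, activity = "transients")
  out <- data.frame(cell = seq_len(n_cells), side_index = NA_real_,
                    si_left = NA_real_, si_right = NA_real_,
                    a_left = NA_real_, a_right = NA_real_)
  for (ci in seq_len(n_cells)) {
    al <- mean_transient_activity(session$z[ci, ], session$transients[[ci]], ml)
    ar <- mean_transient_activity(session$z[ci, ], session$transients[[ci]], mr)
    out$a_left[ci] <- al
    out$a_right[ci] <- ar
    out$side_index[ci] <- side_index(al, ar)
    if (!is.null(tun$left))
      out$si_left[ci] <- suppressWarnings(
        spatial_information(tun$left$raw[ci, ], tun$left$occupancy))
    if (!is.null(tun$right))
      out$si_right[ci] <- suppressWarnings(
        spatial_information(tun$right$raw[ci, ], tun$right$occupancy))
  }
  out
}
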