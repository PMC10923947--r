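#' Baseline correction by running percentile filter
#'
#' Removes slow baseline drift by subtracting the running 10th percentile of
#' the trace over a 30 s centered window. Window edges use the truncated
#' (shrinking) window, avoiding padding artifacts.
#'
#' @param trace numeric vector, raw fluorescence.
#' @param frame_rate Hz.
#' @param window_s window size, s.
#' @param prob percentile as probability.
#' @param stride frames between percentile evaluations; values between grid
#'   points are linearly interpolated. The default (1) evaluates every
#'   frame; a stride well below the window length leaves the estimate of a
#'   30 s-bandwidth baseline essentially unchanged at a fraction of the
#'   cost.
#' @return baseline-corrected trace.
#' @export
baseline_correct <- function(trace, frame_rate, window_s = 30, prob = 0.1,
                             stride = 1L) {
  n <- length(trace)
  if (n < frame_rate) stop("trace shorter than 1 s")
  half <- floor(window_s * frame_rate / 2)
  if (2 * half + 1 > n) stop("percentile window longer than trace")
  grid <- unique(c(seq(1L, n, by = max(1L, as.integer(stride))), n))
  bg <- vapply(grid, function(i) {
    win <- trace[max(1L, i - half):min(n, i + half)]
    window_quantile(win, prob)
  }, numeric(1))
  base <- if (length(grid) == n) bg
          else stats::approx(grid, bg, xout = seq_len(n))$y
  trace - base
}

# Type-7 sample quantile via partial sort (much cheaper than quantile()
# for the many short windows of the running filter).
window_quantile <- function(x, prob) {
  n <- length(x)
  h <- (n - 1) * prob + 1
  lo <- floor(h); hi <- ceiling(h)
  s <- sort(x, partial = unique(c(lo, hi)))
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

#' Iterative z-scoring of a fluorescence trace
#'
#' Standardizes a trace by iteratively estimating the baseline (mean) and
#' noise sd from the sub-threshold portion of the signal: at each iteration
#' samples above baseline + 3 sigma are excluded, until the relative change
#' in sigma falls below 0.1% ((sigma0 - sigma1)/sigma1 < 0.001). The returned
#' z-trace is (trace - baseline) / sigma.
#'
#' @param trace numeric vector.
#' @param max_iter iteration cap; non-convergence raises an error.
#' @return list of class `zscore_result`: `z`, `baseline`, `sigma`,
#'   `n_iterations`.
#' @export
iterative_zscore <- function(trace, max_iter = 100) {
  if (stats::sd(trace) == 0) stop("zero-variance trace cannot be z-scored")
  mu <- mean(trace)
  sigma <- stats::sd(trace)
  for (it in seq_len(max_iter)) {
    keep <- trace <= mu + 3 * sigma
    mu1 <- mean(trace[keep])
    s1 <- stats::sd(trace[keep])
    if (!is.finite(s1) || s1 == 0)
      stop("sub-threshold portion of trace has zero variance")
    done <- abs(sigma - s1) / s1 < 0.001
    mu <- mu1; sigma <- s1
    if (done)
      return(structure(list(z = (trace - mu) / sigma, baseline = mu,
                            sigma = sigma, n_iterations = it),
                       class = "zscore_result"))
  }
  stop("iterative z-scoring did not converge within ", max_iter, " iterations")
}

#' Detect significant calcium transients
#'
#' A significant transient is a maximal run of the z-scored trace strictly
#' exceeding `sigma_threshold` that lasts at least `min_duration` seconds.
#'
#' @param z z-scored trace.
#' @param frame_rate Hz.
#' @param sigma_threshold threshold in z-units (strict inequality).
#' @param min_duration minimum duration, s.
#' @return data.frame of class `transient_set` with columns `start_frame`,
#'   `end_frame`, `peak_frame` (first local maximum; plateaus take their
#'   first frame). Zero rows when no transient qualifies.
#' @export
detect_transients <- function(z, frame_rate, sigma_threshold = 3,
                              min_duration = 0.2) {
  min_len <- ceiling(min_duration * frame_rate)
  above <- z > sigma_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  out <- data.frame(start_frame = starts[keep], end_frame = ends[keep])
  out$peak_frame <- vapply(seq_len(nrow(out)), function(i) {
    seg <- z[out$start_frame[i]:out$end_frame[i]]
    first_peak(seg) + out$start_frame[i] - 1L
  }, integer(1))
  class(out) <- c("transient_set", "data.frame")
  out
}

# Index of the first local maximum of a vector: first position whose value
# is >= both neighbors and > the next distinct value (plateaus resolve to
# their first frame). The last index counts as a peak if the signal rises
# to the end.
first_peak <- function(x) {
  n <- length(x)
  if (n == 1L) return(1L)
  for (i in seq_len(n - 1L)) {
    if (x[i + 1L] < x[i]) {
      while (i > 1L && x[i - 1L] == x[i]) i <- i - 1L
      return(i)
    }
  }
  n
}

#' Rising phases of significant transients
#'
#' Keeps, for each transient, the z signal from threshold crossing to the
#' first peak after the threshold; all other samples are zeroed.
#'
#' @param z z-scored trace.
#' @param transients a [detect_transients()] result.
#' @return numeric vector, same length as `z`.
#' @export
extract_rising_phases <- function(z, transients) {
  out <- numeric(length(z))
  for (i in seq_len(nrow(transients))) {
    idx <- transients$start_frame[i]:transients$peak_frame[i]
    out[idx] <- z[idx]
  }
  out
}

# z masked to transient frames (zero outside transients).
transient_mask_signal <- function(z, transients) {
  out <- numeric(length(z))
  for (i in seq_len(nrow(transients))) {
    idx <- transients$start_frame[i]:transients$end_frame[i]
    out[idx] <- z[idx]
  }
  out
}

#' Mean transient activity within an epoch
#'
#' Mean of the z-scored signal over frames that lie both inside a significant
#' transient and inside the epoch mask (e.g. center-arm travel); 0 when no
#' such frame exists.
#'
#' @param z z-scored trace.
#' @param transients a [detect_transients()] result.
#' @param epoch_mask logical vector over frames.
#' @return scalar, z-units.
#' @export
mean_transient_activity <- function(z, transients, epoch_mask) {
  stopifnot(length(epoch_mask) == length(z))
  inside <- rep(FALSE, length(z))
  for (i in seq_len(nrow(transients)))
    inside[transients$start_frame[i]:transients$end_frame[i]] <- TRUE
  sel <- inside & epoch_mask
  if (!any(sel)) return(0)
  mean(z[sel])
}

#' Preprocess a session: z-scored traces, transients, rising phases
#'
#' Runs [baseline_correct()], [iterative_zscore()], [detect_transients()] and
#' [extract_rising_phases()] over every neuron of a session.
#'
#' @param session a `calcium_session`.
#' @param baseline_stride percentile-evaluation stride for
#'   [baseline_correct()] (default: every 1 s).
#' @return the session with added elements `z` (cells x frames),
#'   `transients` (list of transient sets), `transient_signal` and
#'   `rising` (cells x frames matrices).
#' @export
preprocess_session <- function(session, baseline_stride = NULL) {
  fr <- attr(session$track, "frame_rate")
  if (is.null(baseline_stride)) baseline_stride <- max(1L, round(fr))
  n_cells <- nrow(session$traces)
  n_frames <- ncol(session$traces)
  z <- rising <- tsig <- matrix(0, n_cells, n_frames)
  trs <- vector("list", n_cells)
  for (ci in seq_len(n_cells)) {
    corrected <- baseline_correct(session$traces[ci, ], fr,
                                  stride = baseline_stride)
    zs <- iterative_zscore(corrected)
    tr <- detect_transients(zs$z, fr)
    z[ci, ] <- zs$z
    trs[[ci]] <- tr
    tsig[ci, ] <- transient_mask_signal(zs$z, tr)
    rising[ci, ] <- extract_rising_phases(zs$z, tr)
  }
  session$z <- z
  session$transients <- trs
  session$transient_signal <- tsig
  session$rising <- rising
  session
}
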