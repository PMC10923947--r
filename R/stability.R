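#' Odd/even tuning consistency within a session
#'
#' Computes each neuron's spatial tuning separately for odd and even runs of
#' each direction and correlates them (Pearson), both within the same
#' direction (left-left, right-right) and across directions (left-right,
#' right-left). Neurons with constant tuning in either parity are excluded
#' and counted.
#'
#' @param session a preprocessed session.
#' @param activity activity representation, see [session_tuning()].
#' @return list with per-neuron `same_dir` and `cross_dir` correlations
#'   (averaged over the two direction pairings), their population means,
#'   and `n_excluded`.
#' @export
odd_even_consistency <- function(session, activity = "z") {
  odd <- session_tuning(session, activity = activity, parity = "odd")
  even <- session_tuning(session, activity = activity, parity = "even")
  for (d in c("left", "right"))
    if (is.null(odd[[d]]) || is.null(even[[d]]))
      stop("need >= 1 run per parity and direction (missing: ", d, ")")
  n <- nrow(odd$left$values)
  same <- cross <- matrix(NA_real_, n, 2)
  for (ci in seq_len(n)) {
    same[ci, 1] <- safe_cor(odd$left$values[ci, ], even$left$values[ci, ])
    same[ci, 2] <- safe_cor(odd$right$values[ci, ], even$right$values[ci, ])
    cross[ci, 1] <- safe_cor(odd$left$values[ci, ], even$right$values[ci, ])
    cross[ci, 2] <- safe_cor(odd$right$values[ci, ], even$left$values[ci, ])
  }
  same_n <- rowMeans(same, na.rm = TRUE)
  cross_n <- rowMeans(cross, na.rm = TRUE)
  list(same_dir = same_n, cross_dir = cross_n,
       mean_same = mean(same_n, na.rm = TRUE),
       mean_cross = mean(cross_n, na.rm = TRUE),
       n_excluded = sum(!is.finite(same_n)))
}

#' Cross-day tuning correlation
#'
#' Pearson correlation between each registered neuron's tuning function on
#' two days, computed separately for left and right trajectories, then
#' averaged over directions and neurons to one pooled value.
#'
#' @param tun_a,tun_b [session_tuning()] outputs for the two days, rows
#'   aligned to the same registered neurons.
#' @return list with `per_neuron` (neuron x direction matrix of r),
#'   `per_neuron_pooled`, and the scalar `pooled` mean.
#' @export
cross_day_correlation <- function(tun_a, tun_b) {
  dirs <- intersect(names(tun_a), names(tun_b))
  if (length(dirs) == 0L) stop("no shared directions between days")
  n <- nrow(tun_a[[dirs[1]]]$values)
  if (n == 0L) stop("no registered neurons")
  r <- matrix(NA_real_, n, length(dirs), dimnames = list(NULL, dirs))
  for (d in dirs)
    for (ci in seq_len(n))
      r[ci, d] <- safe_cor(tun_a[[d]]$values[ci, ], tun_b[[d]]$values[ci, ])
  per <- rowMeans(r, na.rm = TRUE)
  list(per_neuron = r, per_neuron_pooled = per,
       pooled = mean(per, na.rm = TRUE))
}

#' Shuffled-identity null for the cross-day correlation
#'
#' Chance-level reference obtained by randomly permuting the neuron order of
#' the first day's tuning functions so that the cross-day correlation pairs
#' different neurons; the pooled correlation is averaged over permutations.
#'
#' @param tun_a,tun_b as in [cross_day_correlation()].
#' @param n_iter number of permutations.
#' @param seed RNG seed.
#' @return mean pooled correlation over permutations.
#' @export
shuffled_cross_day <- function(tun_a, tun_b, n_iter = 100, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  n <- nrow(tun_a[[1]]$values)
  if (n < 2) stop("shuffle null needs >= 2 neurons")
  with_seed(seed, {
    vals <- vapply(seq_len(n_iter), function(i) {
      # permutation without fixed points, so day-1 maps are always paired
      # with a different neuron
      perm <- sample.int(n)
      repeat {
        if (!any(perm == seq_len(n))) break
        perm <- sample.int(n)
      }
      ta <- lapply(tun_a, function(d) {
        d$values <- d$values[perm, , drop = FALSE]
        d$raw <- d$raw[perm, , drop = FALSE]
        d
      })
      cross_day_correlation(ta, tun_b)$pooled
    }, numeric(1))
    mean(vals)
  })
}

#' Simulate representational drift on tuning functions
#'
#' Drift surrogate: starting from observed (or synthetic) 20-bin tuning
#' functions, each neuron's tuning circularly shifts by 1 bin per session
#' with probability `p_drift`, and additive Gaussian per-bin noise of sd
#' `noise_sd` accumulates. Once a neuron's cumulative shift exceeds
#' `regularization_limit` bins, its subsequent drift steps are random -1/+1
#' so the tuning cannot wrap back onto its origin.
#'
#' @param tunings neurons x bins matrix (session 1 state).
#' @param config a [drift_config()]; `n_sessions` counts the returned
#'   sessions including the unmodified first one.
#' @param seed RNG seed.
#' @return list of `config$n_sessions` matrices.
#' @export
simulate_tuning_drift <- function(tunings, config, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  stopifnot(is.matrix(tunings))
  n <- nrow(tunings)
  with_seed(seed, {
    out <- vector("list", config$n_sessions)
    out[[1]] <- tunings
    cum <- rep(0L, n)
    noise_acc <- matrix(0, n, ncol(tunings))
    dirs <- rep(1, n)
    if (config$n_sessions > 1) {
      for (s in 2:config$n_sessions) {
        new_cum <- drift_step(cum, dirs, config$p_drift,
                              config$regularization_limit)
        stepped <- as.integer(new_cum) - cum
        cum <- as.integer(new_cum)
        if (config$noise_sd > 0)
          noise_acc <- noise_acc +
            matrix(stats::rnorm(length(noise_acc), 0, config$noise_sd),
                   n, ncol(tunings))
        m <- tunings
        for (ci in seq_len(n)) m[ci, ] <- circshift(tunings[ci, ], cum[ci])
        out[[s]] <- m + noise_acc
      }
    }
    attr(out, "cumulative_shift") <- cum
    out
  })
}

#' Population vectors at reference spatial bins
#'
#' Extracts the population activity vector (one entry per neuron) at the
#' start, midpoint and endpoint of the outward trajectory, separately for
#' left and right runs: 6 corner points of the population-geometry object.
#'
#' @param tun a [session_tuning()] output (needs both directions).
#' @param bins the three reference bins on the 20-bin grid.
#' @param use `"raw"` (mean activity per bin, default) or `"values"`
#'   (peak-normalized tuning).
#' @return neurons x 6 matrix with columns `left.start`, `left.mid`,
#'   `left.end`, `right.start`, `right.mid`, `right.end`; zero columns are
#'   flagged in `attr(, "zero_corners")`.
#' @export
population_vectors <- function(tun, bins = c(1, 10, 20), use = "raw") {
  stopifnot(length(bins) == 3)
  if (is.null(tun$left) || is.null(tun$right))
    stop("population vectors need runs of both directions")
  pick <- function(d) tun[[d]][[if (use == "raw") "raw" else "values"]][, bins,
                                                                        drop = FALSE]
  pv <- cbind(pick("left"), pick("right"))
  colnames(pv) <- c(paste0("left.", c("start", "mid", "end")),
                    paste0("right.", c("start", "mid", "end")))
  if (nrow(pv) < 2) stop("population vectors need >= 2 neurons")
  pv[!is.finite(pv)] <- 0
  zero <- colSums(pv^2) == 0
  attr(pv, "zero_corners") <- colnames(pv)[zero]
  pv
}

#' Edge-angle matrix of the population-geometry object
#'
#' The 6 population vectors span a geometrical object in neuron-dimension;
#' at each of the 6 corner points, the angles between all 10 pairs of edges
#' to the other 5 corners are computed (radians), ordered lexicographically
#' by the indices of the two far corners.
#'
#' @param pv neurons x 6 matrix of corner points ([population_vectors()]).
#' @return 6 x 10 matrix of angles in \[0, pi\].
#' @export
edge_angle_matrix <- function(pv) {
  stopifnot(is.matrix(pv), ncol(pv) == 6, nrow(pv) >= 2)
  A <- matrix(NA_real_, 6, 10)
  for (c0 in 1:6) {
    others <- setdiff(1:6, c0)
    edges <- pv[, others, drop = FALSE] - pv[, c0]
    norms <- sqrt(colSums(edges^2))
    if (any(norms == 0)) {
      bad <- others[norms == 0][1]
      stop("coincident corner points ", c0, " and ", bad,
           ": zero-length edge")
    }
    k <- 0L
    for (i in 1:4) for (j in (i + 1):5) {
      k <- k + 1L
      cs <- sum(edges[, i] * edges[, j]) / (norms[i] * norms[j])
      A[c0, k] <- acos(pmin(pmax(cs, -1), 1))
    }
  }
  A
}

#' Edge-angle dissimilarity between two days
#'
#' Frobenius norm of the elementwise difference of two edge-angle matrices.
#'
#' @param A_a,A_b 6 x 10 edge-angle matrices.
#' @return non-negative scalar.
#' @export
edge_angle_dissimilarity <- function(A_a, A_b) {
  if (!all(dim(A_a) == dim(A_b))) stop("edge-angle matrix shape mismatch")
  sqrt(sum((A_a - A_b)^2))
}

#' Normalized edge-angle dissimilarity
#'
#' Rescales a cross-day dissimilarity between the within-day (odd/even)
#' dissimilarity and the dissimilarity of shuffled tuning: 0 means the
#' cross-day change equals the within-day variability, 1 means it equals
#' the fully shuffled level.
#'
#' @param cross cross-day `||A||_F`.
#' @param within within-day (odd vs even) `||A||_F`, averaged over days.
#' @param shuffled `||A||_F` of last vs first day after row- and
#'   column-shuffling the tuning functions.
#' @return scalar, ~0 to ~1.
#' @export
normalized_dissimilarity <- function(cross, within, shuffled) {
  if (shuffled <= within)
    stop("degenerate normalization: shuffled (", signif(shuffled, 4),
         ") <= within (", signif(within, 4), ")")
  (cross - within) / (shuffled - within)
}

# Row- and column-shuffle of the tuning matrices of one day.
shuffle_tuning <- function(tun) {
  for (d in names(tun)) {
    m <- tun[[d]]$raw
    m <- m[sample.int(nrow(m)), sample.int(ncol(m)), drop = FALSE]
    tun[[d]]$raw <- m
    v <- tun[[d]]$values
    tun[[d]]$values <- v[sample.int(nrow(v)), sample.int(ncol(v)),
                         drop = FALSE]
  }
  tun
}

#' Population-geometry report across days
#'
#' For each session: the edge-angle matrix of the 6 population vectors
#' (start/mid/end x left/right) and its Frobenius dissimilarity to day 1;
#' within-day dissimilarity from odd vs even runs averaged over days;
#' shuffled reference from row- and column-shuffled tuning of the last vs
#' first day; the normalized dissimilarity; and the Pearson correlation of
#' transient-based population vectors with day 1.
#'
#' @param sessions list of preprocessed sessions (registered neuron rows
#'   aligned across sessions).
#' @param bins reference bins on the 20-bin grid.
#' @param seed RNG seed for the shuffled reference.
#' @return list of class `geometry_report`.
#' @export
geometry_report <- function(sessions, bins = c(1, 10, 20), seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  ns <- length(sessions)
  tun <- lapply(sessions, session_tuning, activity = "z")
  tun_tr <- lapply(sessions, session_tuning, activity = "transients")
  A <- lapply(tun, function(t) edge_angle_matrix(population_vectors(t, bins)))
  cross <- vapply(seq_len(ns), function(s)
    edge_angle_dissimilarity(A[[s]], A[[1]]), numeric(1))
  within_day <- vapply(sessions, function(ss) {
    to <- session_tuning(ss, activity = "z", parity = "odd")
    te <- session_tuning(ss, activity = "z", parity = "even")
    edge_angle_dissimilarity(
      edge_angle_matrix(population_vectors(to, bins)),
      edge_angle_matrix(population_vectors(te, bins)))
  }, numeric(1))
  within <- mean(within_day)
  shuffled <- with_seed(seed, {
    t1 <- shuffle_tuning(tun[[1]])
    tl <- shuffle_tuning(tun[[ns]])
    edge_angle_dissimilarity(
      edge_angle_matrix(population_vectors(t1, bins)),
      edge_angle_matrix(population_vectors(tl, bins)))
  })
  normalized <- vapply(cross, function(cr)
    normalized_dissimilarity(cr, within, shuffled), numeric(1))
  pv1 <- population_vectors(tun_tr[[1]], bins)
  pv_cor <- vapply(seq_len(ns), function(s) {
    pvs <- population_vectors(tun_tr[[s]], bins)
    safe_cor(as.numeric(pv1), as.numeric(pvs))
  }, numeric(1))
  structure(list(frobenius = cross, within_day = within,
                 shuffled = shuffled, normalized = normalized,
                 pv_correlation = pv_cor, bins = bins),
            class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report>\n")
  cat("  ||A^{1,d}||_F: ", paste(signif(x$frobenius, 3), collapse = " "), "\n")
  cat("  within-day:", signif(x$within_day, 3),
      " shuffled:", signif(x$shuffled, 3), "\n")
  cat("  normalized:", paste(signif(x$normalized, 3), collapse = " "), "\n")
  invisible(x)
}
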