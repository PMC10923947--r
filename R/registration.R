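# Render a cell's spatial footprint (anisotropic Gaussian blob) on an
# integer pixel grid given by x/y ranges.
render_footprint <- function(cx, cy, sx, sy, theta, xr, yr) {
  gx <- xr[1]:xr[2]; gy <- yr[1]:yr[2]
  X <- outer(gx - cx, rep(1, length(gy)))
  Y <- outer(rep(1, length(gx)), gy - cy)
  ct <- cos(theta); st <- sin(theta)
  U <- ct * X + st * Y
  V <- -st * X + ct * Y
  exp(-0.5 * ((U / sx)^2 + (V / sy)^2))
}

#' Candidate cell pairs across two sessions
#'
#' All cross-session cell pairs whose footprint centroids lie within
#' `max_dist` pixels of each other (footprints are assumed pre-aligned to a
#' common coordinate grid), with the Pearson correlation of the two
#' footprint images computed on the union of their supports.
#'
#' @param session_a,session_b `calcium_session` objects carrying
#'   `centroids` and `footprint_pars`.
#' @param max_dist centroid distance threshold, pixels (default 31).
#' @return data.frame with `cell_a`, `cell_b`, `dist`, `corr`; zero rows
#'   when no pair qualifies.
#' @export
candidate_pairs <- function(session_a, session_b, max_dist = 31) {
  ca <- session_a$centroids; cb <- session_b$centroids
  out <- list()
  if (nrow(ca) && nrow(cb)) {
    for (i in seq_len(nrow(ca))) {
      d <- sqrt((cb[, 1] - ca[i, 1])^2 + (cb[, 2] - ca[i, 2])^2)
      for (j in which(d < max_dist)) {
        pa <- session_a$footprint_pars[i, ]
        pb <- session_b$footprint_pars[j, ]
        pad <- ceiling(4 * max(pa$blob_sx, pa$blob_sy,
                               pb$blob_sx, pb$blob_sy))
        xr <- round(range(ca[i, 1], cb[j, 1])) + c(-pad, pad)
        yr <- round(range(ca[i, 2], cb[j, 2])) + c(-pad, pad)
        fa <- render_footprint(ca[i, 1], ca[i, 2], pa$blob_sx, pa$blob_sy,
                               pa$blob_theta, xr, yr)
        fb <- render_footprint(cb[j, 1], cb[j, 2], pb$blob_sx, pb$blob_sy,
                               pb$blob_theta, xr, yr)
        supp <- fa > 1e-6 | fb > 1e-6
        out[[length(out) + 1L]] <-
          data.frame(cell_a = i, cell_b = j, dist = d[j],
                     corr = safe_cor(fa[supp], fb[supp]))
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(cell_a = integer(), cell_b = integer(),
                      dist = numeric(), corr = numeric()))
  do.call(rbind, out)
}

# Mixture density over footprint correlations r in (0, 1): "same" cells
# modelled as lognormal in (1 - r), "different" cells as beta in r.
mixture_density <- function(r, w, meanlog, sdlog, a, b) {
  w * stats::dlnorm(pmax(1 - r, 1e-12), meanlog, sdlog) +
    (1 - w) * stats::dbeta(pmin(pmax(r, 1e-12), 1 - 1e-12), a, b)
}

#' Fit the same/different footprint-correlation mixture
#'
#' Fits a weighted sum of a lognormal distribution (modeling same-cell
#' pairs, parameterized in 1 - r) and a beta distribution (modeling
#' different-cell pairs) to the empirical density of candidate-pair
#' footprint correlations, minimizing the mean squared error between the
#' binned data and the mixture.
#'
#' @param correlations candidate-pair footprint correlations (>= 50).
#' @param n_bins equal-width histogram bins on \[0, 1\].
#' @return list of class `mixture_fit`: `weight` (same component),
#'   `meanlog`, `sdlog` (lognormal in 1 - r), `alpha`, `beta` (beta in r),
#'   `mse`.
#' @export
fit_same_different_mixture <- function(correlations, n_bins = 100) {
  r <- correlations[is.finite(correlations)]
  if (length(r) < 50) stop("mixture fit needs >= 50 candidate correlations")
  r <- pmin(pmax(r, 1e-6), 1 - 1e-6)
  br <- seq(0, 1, length.out = n_bins + 1)
  h <- graphics::hist(r, breaks = br, plot = FALSE)
  mids <- h$mids
  dens <- h$density
  obj <- function(par) {
    w <- stats::plogis(par[1])
    f <- mixture_density(mids, w, par[2], exp(par[3]),
                         exp(par[4]), exp(par[5]))
    mean((f - dens)^2)
  }
  # data-driven start: split at r = 0.5, moment-match each side
  hi <- r[r > 0.5]; lo <- r[r <= 0.5]
  informed <- NULL
  if (length(hi) >= 5 && length(lo) >= 5) {
    w0 <- length(hi) / length(r)
    l1r <- log(pmax(1 - hi, 1e-4))
    m_lo <- mean(lo); v_lo <- max(stats::var(lo), 1e-5)
    common <- m_lo * (1 - m_lo) / v_lo - 1
    informed <- c(stats::qlogis(min(max(w0, 0.02), 0.98)),
                  mean(l1r), log(max(stats::sd(l1r), 0.15)),
                  log(max(m_lo * common, 0.2)),
                  log(max((1 - m_lo) * common, 0.2)))
  }
  starts <- list(c(0, log(0.15), log(0.8), log(2), log(2)),
                 c(1, log(0.05), log(0.5), log(1.5), log(3)),
                 c(-1, log(0.3), log(1), log(2), log(1.5)),
                 c(0, log(0.005), log(0.3), log(2), log(20)))
  if (!is.null(informed)) starts <- c(list(informed), starts)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("mixture fit failed")
  par <- best$par
  w <- stats::plogis(par[1])
  if (w > 0.99 || w < 0.01)
    warning("mixture weight at boundary (", signif(w, 3),
            "): distribution may be single-mode")
  else if (stats::pbeta(0.5, exp(par[4]), exp(par[5])) < 0.5)
    warning("different-cell component concentrated above r = 0.5: ",
            "distribution may be single-mode")
  structure(list(weight = w, meanlog = par[2], sdlog = exp(par[3]),
                 alpha = exp(par[4]), beta = exp(par[5]),
                 mse = best$value),
            class = "mixture_fit")
}

#' Posterior probability that a pair is the same cell
#'
#' `P_same` is the posterior weight of the same-cell (lognormal) component
#' of a fitted mixture at the pair's footprint correlation.
#'
#' Two numerical safeguards shape the raw posterior. Correlations in the
#' density gap between the fitted components — where the mixture assigns
#' essentially no probability at all — carry no evidence of being the same
#' cell and get posterior 0 (otherwise the value there is decided by a
#' ratio of two vanishing tails). And the returned `P_same` is made
#' non-decreasing in the correlation by a left-to-right envelope, so a
#' pair more similar than a typical same-cell pair can never score lower
#' than one at the component's mode. Correlations are evaluated at the
#' resolution of the binned fit (half a histogram bin).
#'
#' @param correlation footprint correlation(s) in \[-1, 1\].
#' @param fit a [fit_same_different_mixture()] result.
#' @return probability in \[0, 1\] per correlation.
#' @export
p_same <- function(correlation, fit) {
  if (any(!is.finite(correlation)) ||
      any(correlation < -1) || any(correlation > 1))
    stop("correlation outside [-1, 1]")
  eps <- 0.005                    # half of the 100-bin fit resolution
  raw_post <- function(r) {
    r <- pmin(pmax(r, eps), 1 - eps)
    fs <- fit$weight * stats::dlnorm(1 - r, fit$meanlog, fit$sdlog)
    fd <- (1 - fit$weight) * stats::dbeta(r, fit$alpha, fit$beta)
    ifelse(fs + fd < 1e-6, 0, fs / (fs + fd))
  }
  grid <- seq(0, 1, by = 0.001)
  env <- cummax(raw_post(grid))
  idx <- pmax(findInterval(pmax(correlation, 0), grid), 1L)
  pmax(raw_post(correlation), env[idx])
}

#' Iterative clustering of cells across sessions
#'
#' Builds a registration map from candidate pairs and their `P_same`:
#' sessions are processed chronologically; within a session, cells are
#' visited by descending mean footprint correlation; each cell joins the
#' existing cluster with the highest `P_same` above the threshold (one cell
#' per session per cluster), or founds a new cluster.
#'
#' @param pair_list list over consecutive structures: each element a
#'   data.frame of candidate pairs between session `s` and each earlier
#'   session, as produced by [register_sessions()]; see that function for
#'   the expected layout (columns `session_a`, `cell_a`, `session_b`,
#'   `cell_b`, `corr`, `p_same`).
#' @param n_cells integer vector, number of cells per session.
#' @param threshold minimum `P_same` to join a cluster.
#' @return object of class `registration_map`: data.frame `assignments`
#'   (`cluster`, `session`, `cell`, `p_same`).
#' @export
cluster_cells <- function(pair_list, n_cells, threshold = 0.95) {
  pairs <- do.call(rbind, pair_list)
  n_sessions <- length(n_cells)
  # cluster membership: list of data.frames (session, cell)
  clusters <- list()
  assign_rows <- list()
  member_of <- lapply(n_cells, function(n) rep(NA_integer_, n))
  add <- function(cl, s, cell, p) {
    assign_rows[[length(assign_rows) + 1L]] <<-
      data.frame(cluster = cl, session = s, cell = cell, p_same = p)
    member_of[[s]][cell] <<- cl
    old <- if (cl <= length(clusters)) clusters[[cl]] else NULL
    clusters[[cl]] <<- rbind(old, data.frame(session = s, cell = cell))
  }
  for (cell in seq_len(n_cells[1]))
    add(length(clusters) + 1L, 1L, cell, NA_real_)
  for (s in seq_len(n_sessions)[-1]) {
    ps <- pairs[pairs$session_a < s & pairs$session_b == s, , drop = FALSE]
    ord_score <- tapply(ps$corr, ps$cell_b, mean)
    cells <- seq_len(n_cells[s])
    score <- rep(-Inf, n_cells[s])
    score[as.integer(names(ord_score))] <- ord_score
    for (cell in cells[order(score, decreasing = TRUE)]) {
      cand <- ps[ps$cell_b == cell, , drop = FALSE]
      best_cl <- NA_integer_; best_p <- threshold; best_corr <- -Inf
      if (nrow(cand)) {
        cl_of <- mapply(function(sa, ca) member_of[[sa]][ca],
                        cand$session_a, cand$cell_a)
        for (cl in unique(cl_of[!is.na(cl_of)])) {
          # cluster score: highest P_same over member pairs; ties broken
          # by footprint correlation (deterministic)
          in_cl <- !is.na(cl_of) & cl_of == cl
          p <- max(cand$p_same[in_cl])
          cc <- max(cand$corr[in_cl])
          taken <- any(clusters[[cl]]$session == s)
          if (!taken && (p > best_p ||
                         (p == best_p && is.finite(best_corr) &&
                            cc > best_corr))) {
            best_p <- p; best_cl <- cl; best_corr <- cc
          }
        }
      }
      if (!is.na(best_cl)) add(best_cl, s, cell, best_p)
      else add(length(clusters) + 1L, s, cell, NA_real_)
    }
  }
  structure(list(assignments = do.call(rbind, assign_rows),
                 n_sessions = n_sessions, n_cells = n_cells,
                 threshold = threshold),
            class = "registration_map")
}

#' @export
print.registration_map <- function(x, ...) {
  k <- length(unique(x$assignments$cluster))
  full <- sum(table(x$assignments$cluster) == x$n_sessions)
  cat(sprintf("<registration_map> %d sessions, %d clusters (%d spanning all sessions)\n",
              x$n_sessions, k, full))
  invisible(x)
}

#' Register cells across a list of sessions
#'
#' Full registration pipeline: candidate pairs between every session pair,
#' one pooled same/different mixture fit, per-pair `P_same`, and iterative
#' clustering. When sessions come from the synthetic generator (cell row i
#' is the same ground-truth cell in every session), true-positive and
#' true-negative scores over candidate pairs are reported.
#'
#' @param sessions list of `calcium_session` objects.
#' @param max_dist centroid gate, pixels.
#' @param threshold `P_same` clustering threshold.
#' @param ground_truth if `TRUE`, score the result against the synthetic
#'   identity (row index) ground truth.
#' @return a `registration_map` with extra elements `mixture` and, when
#'   scored, `tp` and `tn`.
#' @export
register_sessions <- function(sessions, max_dist = 31, threshold = 0.95,
                              ground_truth = TRUE) {
  ns <- length(sessions)
  if (ns < 2) stop("registration needs >= 2 sessions")
  pair_list <- list()
  for (a in seq_len(ns - 1)) for (b in (a + 1):ns) {
    cp <- candidate_pairs(sessions[[a]], sessions[[b]], max_dist)
    if (nrow(cp)) {
      cp$session_a <- a; cp$session_b <- b
      pair_list[[length(pair_list) + 1L]] <- cp
    }
  }
  pairs <- do.call(rbind, pair_list)
  fit <- fit_same_different_mixture(pairs$corr)
  pairs$p_same <- p_same(pairs$corr, fit)
  reg <- cluster_cells(list(pairs),
                       vapply(sessions, function(s) nrow(s$traces),
                              integer(1)),
                       threshold)
  reg$mixture <- fit
  if (ground_truth) {
    same_truth <- pairs$cell_a == pairs$cell_b
    asg <- reg$assignments
    cl_of <- function(s, cell)
      asg$cluster[asg$session == s & asg$cell == cell]
    same_pred <- mapply(function(sa, ca, sb, cb)
      cl_of(sa, ca) == cl_of(sb, cb),
      pairs$session_a, pairs$cell_a, pairs$session_b, pairs$cell_b)
    reg$tp <- mean(same_pred[same_truth])
    reg$tn <- mean(!same_pred[!same_truth])
  }
  reg
}

#' Repeatedly active cells of a registration block
#'
#' Clusters that span every session of the block with the cell detected as
#' active on each day.
#'
#' @param reg a `registration_map`.
#' @param sessions the registered sessions (for their `active_mask`).
#' @return matrix clusters x sessions of cell indices (one row per
#'   repeatedly active cell).
#' @export
repeatedly_active <- function(reg, sessions) {
  ns <- reg$n_sessions
  asg <- reg$assignments
  keep <- list()
  for (cl in unique(asg$cluster)) {
    rows <- asg[asg$cluster == cl, ]
    if (nrow(rows) < ns) next
    active <- vapply(seq_len(ns), function(s) {
      cell <- rows$cell[rows$session == s]
      length(cell) == 1 && sessions[[s]]$active_mask[cell]
    }, logical(1))
    if (all(active))
      keep[[length(keep) + 1L]] <-
        vapply(seq_len(ns), function(s) rows$cell[rows$session == s],
               integer(1))
  }
  if (length(keep) == 0L)
    return(matrix(integer(), 0, ns))
  do.call(rbind, keep)
}
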