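#' Build the encoding-model design for a session
#'
#' Concatenates the frames of all correct outward runs and attaches the
#' three categorical predictors of the encoding model: linearized position
#' (50 bins collapsed to 8 levels: first and last bin kept, the middle 48
#' merged into 6 contiguous groups of 8), running speed (per-animal
#' quartiles, 4 levels) and goal location (left/right, 2 levels).
#'
#' @param session a preprocessed session.
#' @param n_pos_bins fine position grid (default 50).
#' @param n_pos_groups coarse position levels after merging (default 8).
#' @return list of class `glm_design`: `frames` (global indices), factors
#'   `pos`, `speed`, `goal`, and `frame_rate`.
#' @export
build_design <- function(session, n_pos_bins = 50, n_pos_groups = 8) {
  runs <- segment_runs(session$track, session$trials)
  if (length(runs) == 0L) stop("no correct outward runs")
  fr_rate <- attr(session$track, "frame_rate")
  frames <- unlist(lapply(runs, `[[`, "frames"))
  u <- unlist(lapply(runs, `[[`, "u"))
  if (anyNA(u)) stop("missing position in outward runs")
  goal <- unlist(lapply(runs, function(r) rep(r$direction, length(r$frames))))
  bin50 <- position_bin(u, n_pos_bins)
  n_mid_groups <- n_pos_groups - 2L
  group_size <- (n_pos_bins - 2L) / n_mid_groups
  pos <- ifelse(bin50 == 1L, 1L,
         ifelse(bin50 == n_pos_bins, n_pos_groups,
                2L + (bin50 - 2L) %/% group_size))
  dx <- c(0, diff(session$track$x)); dy <- c(0, diff(session$track$y))
  spd_all <- sqrt(dx^2 + dy^2) * fr_rate
  spd <- spd_all[frames]
  qs <- stats::quantile(spd, c(0.25, 0.5, 0.75))
  speed <- 1L + findInterval(spd, qs)
  structure(list(frames = frames,
                 pos = factor(pos, levels = seq_len(n_pos_groups)),
                 speed = factor(speed, levels = 1:4),
                 goal = factor(goal, levels = c("left", "right")),
                 frame_rate = fr_rate, n = length(frames)),
            class = "glm_design")
}

# One-hot model matrix for a subset of predictors, each optionally
# circularly shifted along the concatenated frames.
design_matrix <- function(design, include = c("pos", "speed", "goal"),
                          shift = NULL) {
  fac <- list()
  for (p in include) {
    f <- design[[p]]
    if (!is.null(shift[[p]])) f <- f[1 + (seq_len(design$n) - 1 +
                                            shift[[p]]) %% design$n]
    fac[[p]] <- droplevels(f)
  }
  df <- as.data.frame(fac)
  stats::model.matrix(~ ., df)
}

# Random chunk-wise fold assignment: data in 5 s chunks, chunks assigned
# to k folds at random so adjacent frames stay in the same fold.
cv_folds <- function(n, frame_rate, chunk_s = 5, k = 10, seed) {
  chunk_len <- max(1L, round(chunk_s * frame_rate))
  chunk <- (seq_len(n) - 1L) %/% chunk_len + 1L
  n_chunks <- max(chunk)
  if (n_chunks < k) stop("fewer than ", k, " chunks; shorten chunk_s")
  assign <- with_seed(seed, sample(rep(seq_len(k), length.out = n_chunks)))
  assign[chunk]
}

# k-fold CV explained variance for one design matrix and a frames x cells
# response: OLS per fold, r^2 = squared Pearson correlation between
# prediction and held-out data, averaged over folds.
cv_r2 <- function(X, Y, folds) {
  Y <- as.matrix(Y)
  k <- max(folds)
  r2 <- matrix(NA_real_, k, ncol(Y))
  aliased <- 0L
  for (f in seq_len(k)) {
    te <- folds == f
    qr_tr <- qr(X[!te, , drop = FALSE])
    beta <- qr.coef(qr_tr, Y[!te, , drop = FALSE])
    na <- !is.finite(beta)
    if (any(na)) { aliased <- aliased + sum(na[, 1]); beta[na] <- 0 }
    pred <- X[te, , drop = FALSE] %*% beta
    for (m in seq_len(ncol(Y)))
      r2[f, m] <- safe_cor(pred[, m], Y[te, m])^2
  }
  if (aliased > 0)
    message("dropped ", aliased, " aliased design column(s) during CV")
  colMeans(r2, na.rm = TRUE)
}

#' Cross-validated explained variance of the encoding model
#'
#' Fits the linear-link encoding model (ordinary least squares on one-hot
#' factors) with 10-fold cross-validation; data are chunked in 5 s bins
#' randomly assigned to folds so that training and test frames are never
#' adjacent. Explained variance is the squared Pearson correlation between
#' the prediction and the held-out response, averaged over folds.
#'
#' @param design a [build_design()] output.
#' @param response per-frame response for the design frames: vector or
#'   frames x cells matrix (z-scored calcium).
#' @param include predictors to use.
#' @param k folds.
#' @param chunk_s chunk length, s.
#' @param seed RNG seed for the fold assignment.
#' @return r^2 per cell.
#' @export
fit_cv_glm <- function(design, response, include = c("pos", "speed", "goal"),
                       k = 10, chunk_s = 5, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  folds <- cv_folds(design$n, design$frame_rate, chunk_s, k, seed)
  X <- design_matrix(design, include)
  cv_r2(X, response, folds)
}

# Random circular shift offset avoiding near-identity shifts (< min_s s).
random_shift <- function(n, frame_rate, min_s = 5) {
  lo <- ceiling(min_s * frame_rate)
  hi <- n - lo
  if (hi <= lo) stop("design too short for a ", min_s, " s shift")
  sample(lo:hi, 1)
}

#' Variance partitioning: full, single-predictor and shifted models
#'
#' Explained variance of the full three-predictor model, of each
#' single-predictor model, and the drop in explained variance when one
#' predictor is randomly shifted in time within the full model
#' (`dr2 = r2_full - r2_shifted`).
#'
#' @param design a [build_design()] output.
#' @param response frames x cells matrix (or vector).
#' @param k,chunk_s cross-validation settings.
#' @param seed RNG seed (folds and shift offsets).
#' @return list of class `glm_result` with `r2_full` (per cell),
#'   `r2_single` and `dr2_shifted` (predictor x cell matrices).
#' @export
partition_variance <- function(design, response, k = 10, chunk_s = 5, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  preds <- c("pos", "speed", "goal")
  folds <- cv_folds(design$n, design$frame_rate, chunk_s, k,
                    child_seed(seed, 0))
  Y <- as.matrix(response)
  r2_full <- cv_r2(design_matrix(design), Y, folds)
  r2_single <- matrix(NA_real_, 3, ncol(Y), dimnames = list(preds, NULL))
  dr2_shift <- r2_single
  with_seed(child_seed(seed, 1), {
    for (p in preds) {
      r2_single[p, ] <- cv_r2(design_matrix(design, include = p), Y, folds)
      off <- random_shift(design$n, design$frame_rate)
      sh <- stats::setNames(list(off), p)
      r2_sh <- cv_r2(design_matrix(design, shift = sh), Y, folds)
      dr2_shift[p, ] <- r2_full - r2_sh
    }
  })
  structure(list(r2_full = r2_full, r2_single = r2_single,
                 dr2_shifted = dr2_shift),
            class = "glm_result")
}

#' Per-cell predictor significance by permutation
#'
#' For each predictor: `dr2_without = r2_full - r2_without` (model with the
#' predictor removed) is compared with a null distribution of
#' `dr2_shuffled = r2_shifted - r2_without` built from models in which the
#' predictor is randomly circularly shifted in time (`n_shuffle` draws).
#' A cell is significantly modulated by the predictor when its
#' `dr2_without` exceeds 99% of the null values.
#'
#' @param design a [build_design()] output.
#' @param response frames x cells matrix (or vector).
#' @param n_shuffle null draws.
#' @param k,chunk_s cross-validation settings.
#' @param quantile_cut null quantile for the flag (default 0.99).
#' @param seed RNG seed.
#' @return list with `flags` (predictor x cell logical),
#'   `dr2_without` (predictor x cell) and `null_q` (the per-cell null
#'   quantiles).
#' @export
cell_significance <- function(design, response, n_shuffle = 1000, k = 10,
                              chunk_s = 5, quantile_cut = 0.99, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  preds <- c("pos", "speed", "goal")
  folds <- cv_folds(design$n, design$frame_rate, chunk_s, k,
                    child_seed(seed, 0))
  Y <- as.matrix(response)
  m <- ncol(Y)
  r2_full <- cv_r2(design_matrix(design), Y, folds)
  flags <- matrix(NA, 3, m, dimnames = list(preds, NULL))
  dr2_wo <- matrix(NA_real_, 3, m, dimnames = list(preds, NULL))
  null_q <- matrix(NA_real_, 3, m, dimnames = list(preds, NULL))
  with_seed(child_seed(seed, 1), {
    for (p in preds) {
      others <- setdiff(preds, p)
      r2_without <- cv_r2(design_matrix(design, include = others), Y, folds)
      dr2_wo[p, ] <- r2_full - r2_without
      null <- matrix(NA_real_, n_shuffle, m)
      for (d in seq_len(n_shuffle)) {
        off <- random_shift(design$n, design$frame_rate)
        sh <- stats::setNames(list(off), p)
        null[d, ] <- cv_r2(design_matrix(design, shift = sh), Y, folds) -
          r2_without
      }
      q <- apply(null, 2, stats::quantile, probs = quantile_cut,
                 names = FALSE)
      null_q[p, ] <- q
      flags[p, ] <- dr2_wo[p, ] > q
    }
  })
  list(flags = flags, dr2_without = dr2_wo, null_q = null_q,
       r2_full = r2_full)
}
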