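# L2-regularized logistic fit via glmnet with sklearn-style inverse
# regularization C (lambda = 1 / (C * n)). Pads single-feature inputs with
# a zero column because glmnet requires >= 2 predictors.
fit_logistic <- function(x, y, C = 5) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2) stop("outcome decoder needs trials of both classes")
  if (all(apply(x, 2, stats::sd) == 0)) {
    # degenerate features: intercept-only model, predicts the majority class
    maj <- names(which.max(table(y)))
    return(structure(list(fit = NULL, levels = levels(y), majority = maj,
                          padded = FALSE, n_features = ncol(x)),
                     class = "outcome_decoder"))
  }
  padded <- ncol(x) < 2
  if (padded) x <- cbind(x, 0)
  # glmnet warns when a class holds < 8 trials; routine in leave-one-out
  # settings with ~40-trial sessions
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                   lambda = 1 / (C * nrow(x)), standardize = FALSE,
                   maxit = 1e3))
  structure(list(fit = fit, levels = levels(y), padded = padded,
                 n_features = ncol(x)), class = "outcome_decoder")
}

predict_logistic <- function(model, x) {
  x <- as.matrix(x)
  if (is.null(model$fit)) return(rep(model$majority, nrow(x)))
  if (model$padded) x <- cbind(x, 0)
  p <- as.numeric(stats::predict(model$fit, x, type = "response"))
  model$levels[1 + (p > 0.5)]
}

#' Train a cross-day position decoder
#'
#' Linear epsilon-insensitive support-vector regression (cost C = 1) mapping
#' single-frame population activity to linearized position, trained on all
#' same-direction runs of the training day. Left and right runs get
#' separate models; no feature standardization beyond the pipeline's
#' z-scoring.
#'
#' @param act cells x frames activity matrix (z, transient or rising).
#' @param runs [segment_runs()] output for the training session.
#' @param direction `"left"` or `"right"`.
#' @param cost SVR cost parameter.
#' @param max_frames cap on training frames; when the runs hold more, an
#'   evenly spaced subsample is used. The SVR's quadratic-programming cost
#'   grows superlinearly with sample count while decoding accuracy
#'   saturates well below a full 20 Hz session, so training on a few
#'   hundred frames per direction is the practical operating point.
#' @param shuffle_positions if `TRUE` the training positions are permuted
#'   (chance-level control).
#' @param seed RNG seed (needed when `shuffle_positions`).
#' @return object of class `position_decoder`.
#' @export
train_position_decoder <- function(act, runs, direction, cost = 1,
                                   max_frames = 400,
                                   shuffle_positions = FALSE, seed = NULL) {
  sel <- runs[run_directions(runs) == direction]
  if (length(sel) < 2) stop("need >= 2 runs of direction '", direction, "'")
  fr <- unlist(lapply(sel, `[[`, "frames"))
  u <- unlist(lapply(sel, `[[`, "u"))
  if (length(fr) < 2) stop("degenerate training set")
  if (length(fr) > max_frames) {
    idx <- unique(round(seq(1, length(fr), length.out = max_frames)))
    fr <- fr[idx]
    u <- u[idx]
  }
  X <- t(act[, fr, drop = FALSE])
  if (shuffle_positions) {
    if (is.null(seed)) stop("seed required to shuffle positions")
    u <- with_seed(seed, sample(u))
  }
  model <- suppressWarnings(
    e1071::svm(X, u, type = "eps-regression", kernel = "linear",
               cost = cost, epsilon = 0, scale = FALSE))
  structure(list(model = model, direction = direction,
                 n_neurons = nrow(act)), class = "position_decoder")
}

#' Decode linearized position on a target day
#'
#' Applies a day-1 [train_position_decoder()] model to all same-direction
#' runs of the target day and reports the mean absolute error of the
#' predicted linear position.
#'
#' @param decoder a `position_decoder`.
#' @param act cells x frames activity of the target session (same neuron
#'   set as training).
#' @param runs [segment_runs()] output for the target session.
#' @return list with `predictions`, `truth`, and `mae`.
#' @export
decode_position <- function(decoder, act, runs) {
  if (nrow(act) != decoder$n_neurons)
    stop("neuron set mismatch between training and target day")
  sel <- runs[run_directions(runs) == decoder$direction]
  if (length(sel) == 0L) stop("no runs of direction '", decoder$direction, "'")
  fr <- unlist(lapply(sel, `[[`, "frames"))
  u <- unlist(lapply(sel, `[[`, "u"))
  pred <- as.numeric(stats::predict(decoder$model,
                                    t(act[, fr, drop = FALSE])))
  list(predictions = pred, truth = u, mae = mean(abs(pred - u)))
}

# Activity matrix of a preprocessed session for a given representation.
session_activity <- function(session, activity = c("z", "transients",
                                                   "rising")) {
  activity <- match.arg(activity)
  act <- switch(activity, z = session$z,
                transients = session$transient_signal,
                rising = session$rising)
  if (is.null(act)) stop("session not preprocessed")
  act
}

#' Cross-day position decoding, pooled over directions
#'
#' Trains per-direction SVR models on the training session and reports the
#' MAE on the target session, averaged over left and right. Optionally
#' computes a shuffled-position chance reference and an SI-based split
#' (decode separately with the top and bottom half of neurons by spatial
#' information).
#'
#' @param train_session,test_session preprocessed sessions with aligned
#'   neuron rows.
#' @param activity activity representation.
#' @param n_shuffle shuffled-training iterations (0 to skip).
#' @param si_split if `TRUE`, also decode with high-/low-SI halves.
#' @param seed RNG seed.
#' @return list with `mae` (left/right average), `mae_by_direction`,
#'   optional `shuffle_mae` and `si_split` results.
#' @export
position_decoding <- function(train_session, test_session, activity = "z",
                              n_shuffle = 0, si_split = FALSE, seed = 1) {
  act_tr <- session_activity(train_session, activity)
  act_te <- session_activity(test_session, activity)
  runs_tr <- segment_runs(train_session$track, train_session$trials)
  runs_te <- segment_runs(test_session$track, test_session$trials)
  by_direction <- function(rows, shuffle = FALSE, stream = 0) {
    vapply(c("left", "right"), function(d) {
      dec <- train_position_decoder(act_tr[rows, , drop = FALSE], runs_tr, d,
                                    shuffle_positions = shuffle,
                                    seed = child_seed(seed, stream +
                                      match(d, c("left", "right"))))
      decode_position(dec, act_te[rows, , drop = FALSE], runs_te)$mae
    }, numeric(1))
  }
  one <- function(rows, shuffle = FALSE, stream = 0)
    mean(by_direction(rows, shuffle, stream))
  all_rows <- seq_len(nrow(act_tr))
  mbd <- by_direction(all_rows)
  out <- list(mae = mean(mbd), mae_by_direction = mbd)
  if (n_shuffle > 0) {
    out$shuffle_mae <- mean(vapply(seq_len(n_shuffle), function(i)
      one(all_rows, shuffle = TRUE, stream = 10 * i), numeric(1)))
  }
  if (si_split) {
    st <- session_cell_stats(train_session)
    si <- rowMeans(cbind(st$si_left, st$si_right), na.rm = TRUE)
    ord <- order(si, decreasing = TRUE)
    half <- floor(length(ord) / 2)
    out$si_split <- c(high = one(ord[seq_len(half)]),
                      low = one(rev(ord)[seq_len(half)]))
  }
  out
}

#' Per-trial outcome-decoding features
#'
#' Averages each cell's activity over the center epoch of each trial (or,
#' with `until_divergence`, over center-arm frames before the trajectory
#' divergence point).
#'
#' @param session a preprocessed session.
#' @param activity activity representation.
#' @param until_divergence restrict to frames before the divergence point.
#' @return list with `features` (trials x cells) and `labels` (chosen side).
#' @export
outcome_features <- function(session, activity = "z",
                             until_divergence = FALSE) {
  act <- session_activity(session, activity)
  tr <- session$trials
  keep <- which(tr$correct)
  runs <- NULL
  div_u <- NULL
  if (until_divergence) {
    runs <- segment_runs(session$track, session$trials)
    dv <- divergence_point(runs)
    if (is.na(dv$bin)) stop("no divergence point detected")
    div_u <- dv$bin / 50
  }
  feats <- matrix(NA_real_, length(keep), nrow(act))
  for (k in seq_along(keep)) {
    i <- keep[k]
    idx <- tr$run_start[i]:tr$center_end[i]
    if (!is.null(div_u)) {
      run <- runs[[which(vapply(runs, `[[`, numeric(1), "trial") ==
                           tr$trial[i])]]
      n_pre <- which(run$u >= div_u)[1]
      if (is.na(n_pre)) n_pre <- length(run$u)
      idx <- run$frames[seq_len(n_pre)]
    }
    feats[k, ] <- rowMeans(act[, idx, drop = FALSE])
  }
  list(features = feats, labels = tr$choice[keep])
}

#' Train a trial-outcome decoder
#'
#' L2-regularized logistic regression (C = 5) on per-trial per-cell mean
#' center-epoch activity.
#'
#' @param features trials x cells matrix.
#' @param labels chosen side per trial (two classes).
#' @param C inverse regularization strength.
#' @return an `outcome_decoder`.
#' @export
train_outcome_decoder <- function(features, labels, C = 5) {
  if (min(table(labels)) < 2) stop("need >= 2 trials per class")
  fit_logistic(features, labels, C)
}

#' Decode trial outcome on a target day
#'
#' Predicts the chosen side for every trial of the target day with a model
#' trained on day 1, and builds a chance reference by permuting the target
#' day's trial labels.
#'
#' @param model an `outcome_decoder`.
#' @param features trials x cells matrix of the target day.
#' @param labels true chosen sides.
#' @param n_shuffle label permutations for the null.
#' @param seed RNG seed.
#' @return list with `predictions`, `accuracy`, `shuffle_accuracy`.
#' @export
decode_outcome <- function(model, features, labels, n_shuffle = 100,
                           seed = 1) {
  pred <- predict_logistic(model, features)
  acc <- mean(pred == labels)
  shuf <- NA_real_
  if (n_shuffle > 0)
    shuf <- with_seed(seed, mean(vapply(seq_len(n_shuffle), function(i)
      mean(pred == sample(labels)), numeric(1))))
  list(predictions = pred, accuracy = acc, shuffle_accuracy = shuf)
}

#' Leave-one-out outcome decoding within a day
#'
#' Repeatedly holds out one randomly selected trial, trains on the rest and
#' predicts the held-out trial's outcome; accuracy is the fraction of
#' correct predictions over iterations. With `shuffle = TRUE` the training
#' labels are permuted independently on each iteration.
#'
#' @param features trials x cells matrix.
#' @param labels chosen sides.
#' @param n_iter iterations.
#' @param shuffle permute labels each iteration (chance reference).
#' @param C logistic regularization.
#' @param seed RNG seed.
#' @return accuracy in \[0, 1\].
#' @export
loo_outcome_decoding <- function(features, labels, n_iter = 100,
                                 shuffle = FALSE, C = 5, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  n <- nrow(features)
  if (n < 3) stop("leave-one-out needs >= 3 trials")
  with_seed(seed, {
    hits <- vapply(seq_len(n_iter), function(i) {
      test <- sample.int(n, 1)
      lab <- labels[-test]
      if (shuffle) lab <- sample(lab)
      if (min(table(lab)) < 2) return(NA_real_)
      m <- fit_logistic(features[-test, , drop = FALSE], lab, C)
      as.numeric(predict_logistic(m, features[test, , drop = FALSE]) ==
                   labels[test])
    }, numeric(1))
    mean(hits, na.rm = TRUE)
  })
}

#' Single-cell outcome decoding
#'
#' Exhaustive leave-one-out decoding of trial outcome from each cell alone.
#' Cells whose mean feature activity falls below `activity_threshold`
#' (z-units) are excluded and counted.
#'
#' @param features trials x cells matrix (center-epoch means).
#' @param labels chosen sides.
#' @param activity_threshold minimum mean activity, z-units.
#' @param C logistic regularization.
#' @return list with `accuracy` (per cell, `NA` for excluded cells),
#'   `included` logical vector, `n_excluded`.
#' @export
single_cell_decoding <- function(features, labels, activity_threshold = 0.5,
                                 C = 5) {
  n <- nrow(features)
  n_cells <- ncol(features)
  keep <- colMeans(features) >= activity_threshold
  acc <- rep(NA_real_, n_cells)
  for (ci in which(keep)) {
    hits <- vapply(seq_len(n), function(t) {
      lab <- labels[-t]
      if (min(table(lab)) < 2) return(NA_real_)
      m <- fit_logistic(features[-t, ci, drop = FALSE], lab, C)
      as.numeric(predict_logistic(m, features[t, ci, drop = FALSE]) ==
                   labels[t])
    }, numeric(1))
    acc[ci] <- mean(hits, na.rm = TRUE)
  }
  list(accuracy = acc, included = keep, n_excluded = sum(!keep))
}

#' Decoding accuracy as a function of population size
#'
#' Draws random neuron subsets of increasing size, trains the outcome
#' decoder on the training day's subset features and measures accuracy on
#' the target day; mean accuracy per size over draws.
#'
#' @param train_features,train_labels training day.
#' @param test_features,test_labels target day.
#' @param sizes subset sizes (<= population size).
#' @param n_draws random subsets per size.
#' @param C logistic regularization.
#' @param seed RNG seed.
#' @return data.frame with `size` and mean `accuracy`.
#' @export
subset_size_curve <- function(train_features, train_labels,
                              test_features, test_labels,
                              sizes, n_draws = 10, C = 5, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  p <- ncol(train_features)
  if (any(sizes > p)) stop("subset size exceeds population size")
  with_seed(seed, {
    acc <- vapply(sizes, function(sz) {
      mean(vapply(seq_len(n_draws), function(d) {
        cols <- sample.int(p, sz)
        m <- fit_logistic(train_features[, cols, drop = FALSE],
                          train_labels, C)
        mean(predict_logistic(m, test_features[, cols, drop = FALSE]) ==
               test_labels)
      }, numeric(1)))
    }, numeric(1))
    data.frame(size = sizes, accuracy = acc)
  })
}
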