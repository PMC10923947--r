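# Subset a preprocessed session to a set of neuron rows (e.g. the
# repeatedly active ensemble), keeping rows aligned across sessions.
subset_cells <- function(session, rows) {
  for (f in c("traces", "z", "transient_signal", "rising"))
    if (!is.null(session[[f]])) session[[f]] <- session[[f]][rows, ,
                                                             drop = FALSE]
  if (!is.null(session$transients)) session$transients <-
      session$transients[rows]
  session$centroids <- session$centroids[rows, , drop = FALSE]
  session$footprint_pars <- session$footprint_pars[rows, , drop = FALSE]
  session$active_mask <- session$active_mask[rows]
  session
}

#' Run a full synthetic drift experiment end to end
#'
#' Generates a multi-day synthetic experiment, preprocesses every session,
#' registers cells across days, restricts the analyses to the repeatedly
#' active ensemble, and runs the full battery: odd/even consistency,
#' cross-day tuning correlations with their shuffled-identity null,
#' population-geometry report, cross-day position and outcome decoding with
#' chance references, encoding-model variance partitioning with per-cell
#' significance, and per-cell SI / side-index stability.
#'
#' @param n_cells,n_sessions,days,n_trials,drift,active_prob,
#'   trace_noise_sd,footprint_jitter_sd,direction_bias,speed_mod,goal_mod,
#'   prop_tuned passed to [generate_experiment()].
#' @param glm_shuffles permutation draws for GLM cell significance (0 to
#'   skip the significance stage).
#' @param position_shuffles shuffled-training iterations for the position
#'   decoder chance reference (0 to skip).
#' @param use_registration register cells across days and analyze the
#'   repeatedly active ensemble (default); otherwise use the known
#'   synthetic identity.
#' @param seed master seed.
#' @return list of class `drift_report` with per-analysis results and the
#'   ground truth record.
#' @export
run_experiment <- function(n_cells = 100, n_sessions = 13, days = NULL,
                           n_trials = 40,
                           drift = drift_config(n_sessions = n_sessions),
                           active_prob = 1, trace_noise_sd = 0.1,
                           footprint_jitter_sd = 1,
                           direction_bias = 0.6, speed_mod = 0.3,
                           goal_mod = 0.3, prop_tuned = 1,
                           glm_shuffles = 200, position_shuffles = 0,
                           use_registration = TRUE, seed) {
  if (missing(seed)) stop("seed is a mandatory argument")
  exper <- generate_experiment(n_cells = n_cells, n_sessions = n_sessions,
                               days = days, n_trials = n_trials,
                               drift = drift, active_prob = active_prob,
                               trace_noise_sd = trace_noise_sd,
                               footprint_jitter_sd = footprint_jitter_sd,
                               direction_bias = direction_bias,
                               speed_mod = speed_mod, goal_mod = goal_mod,
                               prop_tuned = prop_tuned, seed = seed)
  sessions <- lapply(exper$sessions, preprocess_session)
  ns <- length(sessions)
  days <- exper$ground_truth$days

  registration <- NULL
  if (use_registration && ns >= 2) {
    reg <- register_sessions(exper$sessions,
                             ground_truth = TRUE)
    ra <- repeatedly_active(reg, exper$sessions)
    registration <- list(tp = reg$tp, tn = reg$tn,
                         mixture_weight = reg$mixture$weight,
                         mixture_mse = reg$mixture$mse,
                         n_repeatedly_active = nrow(ra))
    if (nrow(ra) >= 2) {
      sessions <- lapply(seq_len(ns), function(s)
        subset_cells(sessions[[s]], ra[, s]))
    }
  } else {
    active_all <- Reduce(`&`, lapply(sessions, `[[`, "active_mask"))
    sessions <- lapply(sessions, subset_cells, rows = which(active_all))
  }

  tun <- lapply(sessions, session_tuning, activity = "z")
  cons <- odd_even_consistency(sessions[[1]])
  cross <- vapply(seq_len(ns), function(s)
    cross_day_correlation(tun[[1]], tun[[s]])$pooled, numeric(1))
  shuffle_null <- vapply(seq_len(ns), function(s)
    shuffled_cross_day(tun[[1]], tun[[s]], n_iter = 100,
                       seed = child_seed(seed, 300 + s)), numeric(1))
  geometry <- geometry_report(sessions, seed = child_seed(seed, 400))

  pos <- list(mae = rep(NA_real_, ns))
  out_acc <- out_null <- rep(NA_real_, ns)
  feat1 <- outcome_features(sessions[[1]])
  model1 <- train_outcome_decoder(feat1$features, feat1$labels)
  for (s in seq_len(ns)) {
    fs <- outcome_features(sessions[[s]])
    dec <- decode_outcome(model1, fs$features, fs$labels,
                          seed = child_seed(seed, 500 + s))
    out_acc[s] <- dec$accuracy
    out_null[s] <- dec$shuffle_accuracy
  }
  pos_days <- unique(c(1L, ns))
  pos_mae <- rep(NA_real_, ns)
  pos_shuffle <- NA_real_
  for (s in pos_days) {
    pd <- position_decoding(sessions[[1]], sessions[[s]],
                            n_shuffle = if (s == ns) position_shuffles else 0,
                            seed = child_seed(seed, 600 + s))
    pos_mae[s] <- pd$mae
    if (s == ns && position_shuffles > 0) pos_shuffle <- pd$shuffle_mae
  }

  design <- build_design(sessions[[1]])
  Y <- t(sessions[[1]]$z[, design$frames, drop = FALSE])
  glm_part <- partition_variance(design, Y, seed = child_seed(seed, 700))
  glm_sig <- NULL
  if (glm_shuffles > 0)
    glm_sig <- cell_significance(design, Y, n_shuffle = glm_shuffles,
                                 seed = child_seed(seed, 701))

  st1 <- session_cell_stats(sessions[[1]])
  stl <- session_cell_stats(sessions[[ns]])
  cell_stability <- list(
    si_spearman = stats::cor(
      rowMeans(cbind(st1$si_left, st1$si_right), na.rm = TRUE),
      rowMeans(cbind(stl$si_left, stl$si_right), na.rm = TRUE),
      method = "spearman", use = "pairwise.complete.obs"),
    side_index_spearman = stats::cor(st1$side_index, stl$side_index,
                                     method = "spearman",
                                     use = "pairwise.complete.obs"))

  structure(list(
    seed = seed, days = days, n_cells_analyzed = nrow(sessions[[1]]$z),
    registration = registration,
    consistency = list(same = cons$mean_same, cross = cons$mean_cross),
    cross_day_r = cross, shuffle_null_r = shuffle_null,
    geometry = geometry,
    outcome_accuracy = out_acc, outcome_null = out_null,
    position_mae = pos_mae, position_shuffle_mae = pos_shuffle,
    glm = list(r2_full = mean(glm_part$r2_full),
               r2_single = rowMeans(glm_part$r2_single),
               dr2_shifted = rowMeans(glm_part$dr2_shifted),
               frac_significant = if (is.null(glm_sig)) NULL
                                  else rowMeans(glm_sig$flags)),
    cell_stability = cell_stability,
    ground_truth = exper$ground_truth),
    class = "drift_report")
}

#' Summarize a drift report
#'
#' Produces a human-readable text summary and a machine-readable (JSON
#' serializable) twin of the main quantities of a [run_experiment()]
#' report.
#'
#' @param report a `drift_report`.
#' @return list with `text` (character vector of lines) and `json` (named
#'   list of plain numbers/vectors).
#' @export
summarize <- function(report) {
  stopifnot(inherits(report, "drift_report"))
  ns <- length(report$cross_day_r)
  j <- list(
    seed = report$seed,
    n_cells_analyzed = report$n_cells_analyzed,
    days = report$days,
    consistency_same = report$consistency$same,
    consistency_cross = report$consistency$cross,
    cross_day_r = report$cross_day_r,
    shuffle_null_r = report$shuffle_null_r,
    normalized_geometry = report$geometry$normalized,
    pv_correlation = report$geometry$pv_correlation,
    outcome_accuracy = report$outcome_accuracy,
    outcome_null = report$outcome_null,
    position_mae_day1 = report$position_mae[1],
    position_mae_last = report$position_mae[ns],
    glm_r2_full = report$glm$r2_full,
    glm_r2_single = as.list(report$glm$r2_single),
    si_spearman = report$cell_stability$si_spearman,
    side_index_spearman = report$cell_stability$side_index_spearman)
  if (!is.null(report$registration)) {
    j$registration_tp <- report$registration$tp
    j$registration_tn <- report$registration$tn
  }
  txt <- c(
    sprintf("Drift experiment (seed %s): %d sessions over %d days, %d cells analyzed",
            format(report$seed), ns, max(report$days),
            report$n_cells_analyzed),
    sprintf("Odd/even consistency: same-direction %.3f, cross-direction %.3f",
            report$consistency$same, report$consistency$cross),
    sprintf("Cross-day tuning r (day 1 -> last): %.3f (shuffle null %.3f)",
            report$cross_day_r[ns], report$shuffle_null_r[ns]),
    sprintf("Normalized edge-angle dissimilarity (last day): %.3f",
            report$geometry$normalized[ns]),
    sprintf("Outcome decoding day 1 -> last: %.3f (null %.3f)",
            report$outcome_accuracy[ns], report$outcome_null[ns]),
    sprintf("Position MAE day 1 -> last: %.3f", report$position_mae[ns]),
    sprintf("GLM r2: full %.4f | pos %.4f speed %.4f goal %.4f",
            report$glm$r2_full, report$glm$r2_single["pos"],
            report$glm$r2_single["speed"], report$glm$r2_single["goal"]))
  if (!is.null(report$registration))
    txt <- c(txt, sprintf("Registration: TP %.3f TN %.3f (%d repeatedly active)",
                          report$registration$tp, report$registration$tn,
                          report$registration$n_repeatedly_active))
  list(text = txt, json = j)
}

#' @export
print.drift_report <- function(x, ...) {
  cat(paste(summarize(x)$text, collapse = "\n"), "\n")
  invisible(x)
}
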