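#' Write a session to a plain-text directory container
#'
#' Serializes a `calcium_session` as a directory of CSV tables plus a JSON
#' attribute file: `traces.csv` (cells x frames), `track.csv`,
#' `trials.csv`, `footprints.csv` (centroids and blob parameters) and
#' `meta.json` (frame rate, day index, maze geometry, active mask).
#'
#' @param session a `calcium_session`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$traces, file.path(path, "traces.csv"),
                   row.names = FALSE)
  utils::write.csv(session$track, file.path(path, "track.csv"),
                   row.names = FALSE)
  utils::write.csv(session$trials, file.path(path, "trials.csv"),
                   row.names = FALSE)
  fp <- cbind(as.data.frame(session$centroids), session$footprint_pars)
  utils::write.csv(fp, file.path(path, "footprints.csv"), row.names = FALSE)
  g <- attr(session$track, "geometry")
  meta <- list(frame_rate = attr(session$track, "frame_rate"),
               day_index = session$day_index,
               geometry = list(center = g$center, top = g$top, side = g$side),
               active_mask = session$active_mask)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session written by [write_session()]
#'
#' @param path container directory.
#' @return a `calcium_session`.
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  track <- utils::read.csv(file.path(path, "track.csv"),
                           stringsAsFactors = FALSE)
  attr(track, "frame_rate") <- meta$frame_rate
  attr(track, "geometry") <- maze_geometry(meta$geometry$center,
                                           meta$geometry$top,
                                           meta$geometry$side)
  trials <- utils::read.csv(file.path(path, "trials.csv"),
                            stringsAsFactors = FALSE)
  fp <- utils::read.csv(file.path(path, "footprints.csv"))
  structure(list(
    traces = as.matrix(utils::read.csv(file.path(path, "traces.csv"))),
    track = track, trials = trials,
    day_index = as.integer(meta$day_index),
    centroids = as.matrix(fp[, c("x", "y")]),
    footprint_pars = fp[, c("blob_sx", "blob_sy", "blob_theta")],
    active_mask = as.logical(meta$active_mask)),
    class = "calcium_session")
}

#' Write the ground-truth sidecar of a synthetic experiment
#'
#' @param ground_truth the `ground_truth` element of
#'   [generate_experiment()].
#' @param path JSON file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  out <- list(cells = ground_truth$cells,
              drift_bins = ground_truth$drift_bins,
              days = ground_truth$days,
              drift = unclass(ground_truth$drift),
              seed = ground_truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
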