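# Plain-text interchange: track tables and segment tables as CSV with the
# schema (track_id, frame, time_s, x_um, y_um, orientation_rad, length_um,
# width_um), so external trackers can feed the segmentation stage.

#' Write trajectories to a track CSV
#'
#' @param trajs a [trajectory()] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    cbind(track_id = attr(tr, "track_id"), as.data.frame(tr))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a track CSV into trajectory objects
#'
#' Expects the column schema written by [write_tracks()]. The frame rate
#' is inferred from the median time step unless given.
#'
#' @param path CSV path.
#' @param frame_rate frames per second; `NULL` infers it from `time_s`.
#' @param orientation orientation convention of the stored angles.
#' @return a list of [trajectory()] objects.
#' @export
read_tracks <- function(path, frame_rate = NULL,
                        orientation = c("directional", "axial")) {
  orientation <- match.arg(orientation)
  df <- utils::read.csv(path)
  need <- c("track_id", "frame", "time_s", "x_um", "y_um",
            "orientation_rad", "length_um", "width_um")
  if (!all(need %in% names(df)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$track_id), function(d) {
    d <- d[order(d$frame), ]
    fr <- frame_rate %||% round(1 / stats::median(diff(d$time_s)))
    trajectory(d$frame, d$time_s, d$x_um, d$y_um, d$orientation_rad,
               d$length_um, d$width_um, track_id = d$track_id[1],
               frame_rate = fr, orientation = orientation)
  })
}

#' Write run/tumble segments to CSV
#'
#' @param segment_sets a `segment_set` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segment_sets, path) {
  if (inherits(segment_sets, "segment_set")) segment_sets <- list(segment_sets)
  rows <- lapply(segment_sets, function(s)
    cbind(track_id = s$track_id, s$segments))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
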