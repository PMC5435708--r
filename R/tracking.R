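# Linking per-frame detections into tracks, smoothing, and resolving the
# body-axis orientation into a full swimming direction.

#' Link per-frame detections into tracks
#'
#' Particles are linked when their pixel masks overlap in consecutive
#' frames (the `"centroid"` fallback links the nearest centroid within a
#' gate, for detections without masks). Any frame at which links merge or
#' branch (a particle with two predecessors or two successors, e.g. two
#' cells crossing) breaks every link involved, so crossing tracks are split
#' there. Tracks shorter than `min_duration` seconds are removed.
#'
#' @param detections a `particle_observations` data frame (see
#'   [detect_particles()]); for `"overlap"` linking it must carry the
#'   `pixels` list column and a `dims` attribute.
#' @param frame_rate frames per second of the recording.
#' @param min_duration minimum track duration in seconds (default 2).
#' @param method `"overlap"` (default) or `"centroid"`.
#' @param max_dist centroid gate in um for `"centroid"` linking; defaults
#'   to the smallest detected cell length.
#' @return list of [trajectory()] objects with `"axial"` orientation.
#' @export
link_tracks <- function(detections, frame_rate = 30, min_duration = 2,
                        method = c("overlap", "centroid"), max_dist = NULL) {
  method <- match.arg(method)
  stopifnot(is.data.frame(detections))
  if (!nrow(detections)) return(list())
  frames <- sort(unique(detections$frame))
  det_idx <- split(seq_len(nrow(detections)), detections$frame)
  dims <- attr(detections, "dims")
  if (method == "overlap" && (is.null(detections$pixels) || is.null(dims)))
    stop("overlap linking needs pixel masks; use method = 'centroid'")
  if (method == "centroid" && is.null(max_dist))
    max_dist <- max(min(detections$length_um), 1e-6)

  n <- nrow(detections)
  succ <- vector("list", n)
  pred_count <- integer(n)
  for (k in seq_len(length(frames) - 1L)) {
    if (frames[k + 1L] != frames[k] + 1L) next  # no gap closing
    cur <- det_idx[[as.character(frames[k])]]
    nxt <- det_idx[[as.character(frames[k + 1L])]]
    if (is.null(cur) || is.null(nxt)) next
    if (method == "overlap") {
      lookup <- integer(prod(dims))
      for (j in nxt) lookup[detections$pixels[[j]]] <- j
      for (i in cur) {
        hits <- unique(lookup[detections$pixels[[i]]])
        hits <- hits[hits > 0L]
        succ[[i]] <- hits
        pred_count[hits] <- pred_count[hits] + 1L
      }
    } else {
      for (i in cur) {
        d2 <- (detections$x_um[nxt] - detections$x_um[i])^2 +
          (detections$y_um[nxt] - detections$y_um[i])^2
        ok <- which(d2 <= max_dist^2)
        if (length(ok)) {
          j <- nxt[ok[which.min(d2[ok])]]
          succ[[i]] <- j
          pred_count[j] <- pred_count[j] + 1L
        }
      }
    }
  }
  # break all links at merges (>= 2 predecessors) and splits (>= 2 successors)
  next_of <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    s <- succ[[i]]
    if (length(s) == 1L && pred_count[s] == 1L) next_of[i] <- s
  }
  has_pred <- rep(FALSE, n)
  has_pred[stats::na.omit(next_of)] <- TRUE
  tracks <- list()
  for (i in seq_len(n)) {
    if (has_pred[i]) next
    chain <- i
    while (!is.na(next_of[chain[length(chain)]]))
      chain <- c(chain, next_of[chain[length(chain)]])
    tracks[[length(tracks) + 1L]] <- chain
  }
  out <- list()
  for (tid in seq_along(tracks)) {
    ch <- tracks[[tid]]
    dur <- (length(ch) - 1L) / frame_rate
    if (dur < min_duration) next
    d <- detections[ch, , drop = FALSE]
    out[[length(out) + 1L]] <- trajectory(
      d$frame, d$frame / frame_rate, d$x_um, d$y_um,
      wrap_pi(d$orientation_rad), d$length_um, d$width_um,
      track_id = length(out) + 1L, frame_rate = frame_rate,
      orientation = "axial")
  }
  out
}

# centred moving average with shrinking windows at the ends
.moving_mean <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a track with a centred moving average
#'
#' Positions are smoothed with a centred moving average (default five
#' frames, a 0.17 s window at 30 fps, enough to average out body wobble);
#' windows shrink at the track ends. The orientation is smoothed
#' circularly: on the doubled angle for axial orientations, directly on
#' the unit vector for directional ones.
#'
#' @param traj a [trajectory()].
#' @param window odd window length in frames.
#' @return the smoothed trajectory.
#' @export
smooth_track <- function(traj, window = 5L) {
  stopifnot(inherits(traj, "trajectory"), window >= 1, window %% 2 == 1)
  n <- nrow(traj)
  if (window > n) stop("smoothing window longer than the track")
  half <- (window - 1L) %/% 2L
  traj$x_um <- .moving_mean(traj$x_um, half)
  traj$y_um <- .moving_mean(traj$y_um, half)
  mult <- if (identical(attr(traj, "orientation"), "axial")) 2 else 1
  s <- .moving_mean(sin(mult * traj$orientation_rad), half)
  c <- .moving_mean(cos(mult * traj$orientation_rad), half)
  th <- atan2(s, c) / mult
  traj$orientation_rad <- if (mult == 2) th else wrap_2pi(th)
  attr(traj, "smoothed_window") <- window
  traj
}

#' Resolve body-axis orientation into a swimming direction
#'
#' For elongated cells (aspect ratio at or above the threshold) the axial
#' orientation (known modulo pi) is disambiguated by the direction of
#' motion: the head is the end within a right angle of the displacement,
#' with hysteresis across frames so that noise near the quadrant boundary
#' and stationary episodes do not produce spurious pi flips. For short
#' cells, whose moment-based orientation is unreliable, the orientation is
#' taken from the centroid displacement across each triplet of consecutive
#' frames. Stationary frames inherit the previous orientation.
#'
#' @param traj a smoothed [trajectory()].
#' @param aspect_ratio_threshold aspect ratio above which the axial
#'   orientation is trusted (default 3).
#' @param min_step displacement (um) below which a frame counts as
#'   stationary.
#' @return the trajectory with `orientation_rad` in `[0, 2pi)` and
#'   orientation attribute `"directional"`.
#' @export
resolve_orientation <- function(traj, aspect_ratio_threshold = 3,
                                min_step = 1e-6) {
  stopifnot(inherits(traj, "trajectory"))
  n <- nrow(traj)
  if (n < 3L) stop("track too short to resolve orientation")
  x <- traj$x_um; y <- traj$y_um
  dx <- c(x[2] - x[1], x[3:n] - x[1:(n - 2)], x[n] - x[n - 1])
  dy <- c(y[2] - y[1], y[3:n] - y[1:(n - 2)], y[n] - y[n - 1])
  mag <- sqrt(dx^2 + dy^2)
  phi <- atan2(dy, dx)
  ar <- stats::median(traj$length_um) / stats::median(traj$width_um)
  th <- numeric(n)
  if (ar < aspect_ratio_threshold) {
    last <- NA_real_
    for (i in seq_len(n)) {
      if (mag[i] > min_step) last <- phi[i]
      th[i] <- if (is.na(last)) 0 else last
    }
    if (is.na(th[1])) th[] <- 0
  } else {
    axial <- traj$orientation_rad
    prev <- NA_real_
    for (i in seq_len(n)) {
      cand <- c(axial[i], axial[i] + pi)
      if (mag[i] > min_step) {
        sc <- abs(wrap_pi(cand - phi[i]))
        pick <- which.min(sc)
        # hysteresis: near the perpendicular boundary keep head continuity
        if (!is.na(prev) && abs(sc[1] - sc[2]) < 0.35) {
          pick <- which.min(abs(wrap_pi(cand - prev)))
        }
      } else if (!is.na(prev)) {
        pick <- which.min(abs(wrap_pi(cand - prev)))
      } else pick <- 1L
      th[i] <- cand[pick]
      prev <- th[i]
    }
  }
  traj$orientation_rad <- wrap_2pi(th)
  attr(traj, "orientation") <- "directional"
  traj
}
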