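# The core method: discriminate motile from non-motile cells and segment
# motile tracks into runs and tumbles using thresholds set by the Brownian
# expectations for the cell's own prolate-spheroid geometry, rather than any
# fixed empirical cutoff.

#' Speed and angular-velocity thresholds from Brownian expectations
#'
#' Over a window t, the displacement of a passive spheroid along its major
#' axis is N(0, 2 D_t t) and its orientation change is N(0, 2 D_r t).
#' The thresholds are the values whose probability of being produced by
#' Brownian motion alone is below `p`: with the default `"magnitude"` tail
#' convention the half-normal upper p-quantile z_{1-p/2} sigma / t, so that
#' exactly a fraction p of Brownian windows exceeds each criterion; the
#' `"signed"` variant uses z_{1-p} (the two differ by ~10%).
#'
#' Any observed speed above the speed threshold cannot reasonably be
#' Brownian and marks active running; any angular velocity above the
#' angular threshold marks active tumbling.
#'
#' @param geom an [ellipsoid_geometry()] (per-cell: the track's median
#'   geometry).
#' @param medium a [medium()].
#' @param window evaluation window t in seconds (default 0.17, the
#'   five-frame smoothing window at 30 fps).
#' @param p Brownian exceedance probability (default 0.01).
#' @param tail quantile convention, see above.
#' @return an object of class `brownian_thresholds` with
#'   `speed_threshold` (um/s), `angular_velocity_threshold` (rad/s),
#'   `sigma_t` (um), `sigma_r` (rad) and the ingredients needed to
#'   re-evaluate the criteria at other window lengths.
#' @export
brownian_thresholds <- function(geom, medium, window = 0.17, p = 0.01,
                                tail = c("magnitude", "signed")) {
  tail <- match.arg(tail)
  if (!is.numeric(window) || window <= 0) stop("window must be > 0 s")
  stopifnot(p > 0, p < 1)
  ds <- diffusivities(geom, medium)
  z <- if (tail == "magnitude") stats::qnorm(1 - p / 2) else stats::qnorm(1 - p)
  sigma_t <- sqrt(2 * ds$D_t_major * window)
  sigma_r <- sqrt(2 * ds$D_r * window)
  structure(list(window = window, p = p, tail = tail, z = z,
                 D_t_major = ds$D_t_major, D_r = ds$D_r,
                 sigma_t = sigma_t, sigma_r = sigma_r,
                 speed_threshold = z * sigma_t / window,
                 angular_velocity_threshold = z * sigma_r / window),
            class = "brownian_thresholds")
}

#' @export
print.brownian_thresholds <- function(x, ...) {
  cat(sprintf("Brownian thresholds (t = %.3g s, p = %.3g, %s tail):\n  speed %.3g um/s, angular velocity %.3g rad/s\n",
              x$window, x$p, x$tail, x$speed_threshold,
              x$angular_velocity_threshold))
  invisible(x)
}

# frame-wise displacement projected on the body major axis (um per frame)
.axial_displacements <- function(traj) {
  n <- nrow(traj)
  if (n < 2L) stop("track too short")
  if (is.null(traj$orientation_rad) || anyNA(traj$orientation_rad))
    stop("track lacks orientations; run resolve_orientation() first")
  dx <- diff(traj$x_um); dy <- diff(traj$y_um)
  u <- traj$orientation_rad[-n]
  dx * cos(u) + dy * sin(u)
}

#' Classify a track as motile or non-motile
#'
#' A particle moving purely by Brownian motion has frame-to-frame
#' displacements d along its major axis with mean 0 and
#' var(d) <= 2 D_t t. The track is called motile if either null is
#' rejected: a two-sided t-test of mean(d) = 0, or a one-sided chi-square
#' test of var(d) <= 2 D_t t, each at level `alpha`. D_t is the major-axis
#' translational diffusivity for the track's median geometry.
#'
#' @param traj a [trajectory()] with orientations, at least 2 s long.
#' @param medium a [medium()].
#' @param alpha significance level of each test (default 0.001; the
#'   union of the two tests gives a Brownian false-positive rate of about
#'   2 alpha).
#' @return `"motile"` or `"nonmotile"`, with attribute `p_values`.
#' @export
classify_motile <- function(traj, medium, alpha = 0.001) {
  stopifnot(inherits(traj, "trajectory"))
  fr <- attr(traj, "frame_rate")
  if ((nrow(traj) - 1) / fr < 2) stop("classification requires tracks of at least 2 s")
  d <- .axial_displacements(traj)
  n <- length(d)
  dt <- 1 / fr
  D_t <- diffusivities(track_geometry(traj), medium)$D_t_major
  s <- stats::sd(d)
  p_t <- if (s > 0) 2 * stats::pt(-abs(mean(d) / (s / sqrt(n))), n - 1) else 1
  p_var <- stats::pchisq((n - 1) * stats::var(d) / (2 * D_t * dt), n - 1,
                         lower.tail = FALSE)
  verdict <- if (p_t < alpha || p_var < alpha) "motile" else "nonmotile"
  attr(verdict, "p_values") <- c(t_test = p_t, variance_test = p_var)
  verdict
}

#' Segment a motile track into runs and tumbles
#'
#' Over a sliding window matched to `thresholds$window`, each frame gets a
#' speed (the magnitude of the summed axial displacement projections over
#' the window, divided by the window length) and an angular velocity (the
#' wrapped orientation change over the window divided by its length). A
#' frame is part of a run when speed exceeds the speed threshold AND the
#' angular velocity stays below the angular threshold; every other frame
#' is a tumble. Contiguous labels form segments; the first and last
#' segment of a track are flagged incomplete, and tumble angles (the
#' signed angle between the mean directions of the flanking runs) are
#' reported only for tumbles flanked by complete runs.
#'
#' The criteria are evaluated with sigma recomputed at the realized window
#' length (a whole number of frames), so the Brownian exceedance
#' probability is exactly `p` whatever the frame rate.
#'
#' @param traj a smoothed, orientation-resolved [trajectory()].
#' @param thresholds a [brownian_thresholds()] for the track's geometry.
#' @return an object of class `segment_set`: data frame `segments` with
#'   columns `kind`, `start_frame`, `end_frame`, `t_start`, `t_end`,
#'   `duration`, `complete`, `mean_speed` (runs), `angle` (flanked
#'   tumbles), plus the per-frame `labels`.
#' @export
segment_track <- function(traj, thresholds) {
  stopifnot(inherits(traj, "trajectory"), inherits(thresholds, "brownian_thresholds"))
  fr <- attr(traj, "frame_rate")
  dt <- 1 / fr
  span <- max(1L, round(thresholds$window * fr))
  n <- nrow(traj)
  if (n <= span) stop("track shorter than the evaluation window")
  d_ax <- .axial_displacements(traj)
  cs <- c(0, cumsum(d_ax))
  tspan <- span * dt
  disp <- cs[(span + 1):n] - cs[seq_len(n - span)]
  speed_w <- abs(disp) / tspan
  th <- traj$orientation_rad
  dth <- wrap_pi(th[(span + 1):n] - th[seq_len(n - span)])
  angvel_w <- abs(dth) / tspan
  s_thr <- thresholds$z * sqrt(2 * thresholds$D_t_major * tspan) / tspan
  a_thr <- thresholds$z * sqrt(2 * thresholds$D_r * tspan) / tspan
  lab_w <- ifelse(speed_w > s_thr & angvel_w < a_thr, "run", "tumble")
  # window j covers frames j..j+span; assign to its centre frame
  centre <- seq_len(n - span) + span %/% 2L
  labels <- rep(NA_character_, n)
  labels[centre] <- lab_w
  labels[seq_len(centre[1] - 1L)] <- lab_w[1]
  labels[(centre[length(centre)] + 1L):n] <- lab_w[length(lab_w)]
  speed_f <- rep(NA_real_, n)
  speed_f[centre] <- speed_w
  speed_f[seq_len(centre[1] - 1L)] <- speed_w[1]
  speed_f[(centre[length(centre)] + 1L):n] <- speed_w[length(speed_w)]

  # events shorter than about half the evaluation window are below the
  # resolution of the windowed criteria; such flickers are merged into
  # their surroundings before segments are formed
  min_frames <- max(1L, span %/% 2L)
  r <- rle(labels)
  repeat {
    if (length(r$values) < 3L) break
    interior <- 2:(length(r$values) - 1L)
    short <- interior[r$lengths[interior] < min_frames]
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    r$values[k] <- r$values[k - 1L]
    r <- rle(inverse.rle(r))
  }
  labels <- inverse.rle(r)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nseg <- length(r$values)
  half <- span %/% 2L
  seg <- data.frame(kind = r$values,
                    start_frame = traj$frame[starts],
                    end_frame = traj$frame[ends],
                    t_start = traj$time_s[starts],
                    t_end = traj$time_s[ends],
                    duration = r$lengths * dt,
                    complete = !(seq_len(nseg) %in% c(1L, nseg)),
                    mean_speed = NA_real_, angle = NA_real_)
  for (i in seq_len(nseg)) {
    if (seg$kind[i] != "run") next
    # average windows fully interior to the run where possible, so boundary
    # windows straddling the adjacent tumble do not dilute the run speed
    idx <- starts[i]:ends[i]
    interior <- idx[idx >= starts[i] + half & idx <= ends[i] - (span - half)]
    if (!length(interior)) interior <- idx
    # median across windows: robust to sub-resolution pauses merged into
    # the run, which would otherwise dilute its speed
    seg$mean_speed[i] <- stats::median(speed_f[interior])
  }
  # mean run direction for tumble angles: frames within half a window of
  # the segment boundary already mix in the adjacent tumble's rotation, so
  # they are dropped whenever the run is long enough to afford it
  run_dir <- function(a, b) {
    if (b - a + 1L > 2L * half) circ_mean(th[(a + half):(b - half)])
    else circ_mean(th[a:b])
  }
  for (i in seq_len(nseg)) {
    if (seg$kind[i] != "tumble" || i == 1L || i == nseg) next
    if (!seg$complete[i - 1L] || !seg$complete[i + 1L]) next
    # runs shorter than the evaluation window cannot anchor a direction
    if (r$lengths[i - 1L] < span || r$lengths[i + 1L] < span) next
    dir_prev <- run_dir(starts[i - 1L], ends[i - 1L])
    dir_next <- run_dir(starts[i + 1L], ends[i + 1L])
    seg$angle[i] <- wrap_pi(dir_next - dir_prev)
  }
  structure(list(segments = seg, labels = labels,
                 track_id = attr(traj, "track_id"),
                 window = thresholds$window, thresholds = thresholds),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  s <- x$segments
  cat(sprintf("segment set (track %s): %d runs, %d tumbles (%d complete segments)\n",
              format(x$track_id), sum(s$kind == "run"),
              sum(s$kind == "tumble"), sum(s$complete)))
  invisible(x)
}

#' Pool segment statistics into a motility summary
#'
#' Complete runs contribute durations and mean speeds; complete tumbles
#' contribute durations; tumbles flanked by complete runs contribute
#' angles. Durations get exponential rate MLEs (1/mean), speeds lognormal
#' MLEs, and tumble angles both the mean cosine (sensitive to reversals)
#' and the mean absolute cosine (the shape-restriction statistic).
#'
#' @param segment_sets a `segment_set` or list of them.
#' @param classifications optional character vector of
#'   motile/nonmotile verdicts for the whole population, used to report
#'   the motile fraction.
#' @return an object of class `motility_summary`.
#' @export
summarize_motility <- function(segment_sets, classifications = NULL) {
  if (inherits(segment_sets, "segment_set")) segment_sets <- list(segment_sets)
  segs <- do.call(rbind, lapply(segment_sets, `[[`, "segments"))
  runs <- segs[segs$kind == "run" & segs$complete, , drop = FALSE]
  tums <- segs[segs$kind == "tumble" & segs$complete, , drop = FALSE]
  angles <- tums$angle[!is.na(tums$angle)]
  if (!nrow(runs) && !nrow(tums)) stop("no complete segments to summarize")
  lnorm <- if (nrow(runs)) {
    lv <- log(runs$mean_speed[runs$mean_speed > 0])
    c(meanlog = mean(lv), sdlog = stats::sd(lv))
  } else c(meanlog = NA_real_, sdlog = NA_real_)
  structure(list(
    n_runs = nrow(runs), n_tumbles = nrow(tums), n_angles = length(angles),
    run_time_mean = mean(runs$duration), run_time_sd = stats::sd(runs$duration),
    run_time_rate = 1 / mean(runs$duration),
    run_speed_mean = mean(runs$mean_speed), run_speed_sd = stats::sd(runs$mean_speed),
    run_speed_lognormal = lnorm,
    tumble_time_mean = if (nrow(tums)) mean(tums$duration) else NA_real_,
    tumble_time_sd = if (nrow(tums)) stats::sd(tums$duration) else NA_real_,
    tumble_time_rate = if (nrow(tums)) 1 / mean(tums$duration) else NA_real_,
    mean_cos = if (length(angles)) mean(cos(angles)) else NA_real_,
    mean_abs_cos = if (length(angles)) mean(abs(cos(angles))) else NA_real_,
    sd_cos = if (length(angles)) stats::sd(cos(angles)) else NA_real_,
    fraction_motile = if (is.null(classifications)) NA_real_ else
      mean(classifications == "motile")),
    class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("motility summary: %d runs, %d tumbles (%d tumble angles)\n",
              x$n_runs, x$n_tumbles, x$n_angles))
  cat(sprintf("  run time %.2f +/- %.2f s, run speed %.1f +/- %.1f um/s\n",
              x$run_time_mean, x$run_time_sd, x$run_speed_mean, x$run_speed_sd))
  if (!is.na(x$tumble_time_mean))
    cat(sprintf("  tumble time %.2f +/- %.2f s, mean cos %.2f, mean |cos| %.2f\n",
                x$tumble_time_mean, x$tumble_time_sd, x$mean_cos, x$mean_abs_cos))
  if (!is.na(x$fraction_motile))
    cat(sprintf("  fraction motile %.1f%%\n", 100 * x$fraction_motile))
  invisible(x)
}
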