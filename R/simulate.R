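# Ground-truth simulator: 2-D run-and-tumble and pure-Brownian trajectories
# of prolate-spheroid cells, Euler-Maruyama at an oversampled internal step,
# downsampled to the video frame rate.

#' Tumble-angle models
#'
#' `tumble_uniform()` draws tumble angles uniformly on (-pi, pi];
#' `tumble_truncated(alpha_m)` uniformly on (-alpha_m, alpha_m];
#' `tumble_forward(kappa)` from a forward-biased wrapped normal with
#' concentration kappa (sd = 1/sqrt(kappa) before wrapping).
#'
#' @param alpha_m maximum tumble angle in radians, in (0, pi].
#' @param kappa concentration of the forward bias, > 0.
#' @return a `tumble_model` object used by [motility_parameters()].
#' @export
tumble_uniform <- function() structure(list(type = "uniform"), class = "tumble_model")

#' @rdname tumble_uniform
#' @export
tumble_truncated <- function(alpha_m) {
  stopifnot(alpha_m > 0, alpha_m <= pi)
  structure(list(type = "truncated", alpha_m = alpha_m), class = "tumble_model")
}

#' @rdname tumble_uniform
#' @export
tumble_forward <- function(kappa) {
  stopifnot(kappa > 0)
  structure(list(type = "forward", kappa = kappa), class = "tumble_model")
}

.draw_tumble_angles <- function(model, n) {
  switch(model$type,
         uniform = stats::runif(n, -pi, pi),
         truncated = stats::runif(n, -model$alpha_m, model$alpha_m),
         forward = wrap_pi(stats::rnorm(n, 0, 1 / sqrt(model$kappa))),
         stop("unknown tumble model"))
}

#' Motility parameters of a simulated cell
#'
#' Defaults reproduce the normal-size population: exponential run and tumble
#' durations with means 0.6 s and 0.4 s, lognormal run speeds with mean
#' 16.1 and sd 6.1 um/s (median ~15.1 um/s, shape 0.366), uniform tumble
#' angles, and tumbles that complete their drawn angle within their drawn
#' duration (implied mean rotation rate ~3.93 rad/s, the conservative
#' mean-angle / mean-duration estimate).
#'
#' @param mean_run_time mean run duration in s.
#' @param mean_tumble_time mean tumble duration in s.
#' @param run_speed_median median of the lognormal run-speed distribution,
#'   um/s. 0 gives a cell with zero active speed.
#' @param run_speed_shape lognormal shape (sd of log speed); 0 makes the
#'   speed degenerate at the median.
#' @param tumble_angle_model a `tumble_model`, see [tumble_uniform()].
#' @param reversal_probability probability that a new run starts with the
#'   opposite pole leading (an extra pi flip), in `[0, 1]`.
#' @param active_tumble_rate body rotation rate during an active tumble,
#'   rad/s. The default `NULL` turns each tumble at the constant rate that
#'   completes its drawn target angle exactly within its drawn exponential
#'   duration, so durations stay exponential and realized angles equal the
#'   drawn ones (the implied mean rate is mean angle / mean duration, the
#'   conservative estimate for the normal-size population). A numeric value
#'   instead rotates at that fixed rate and ends the tumble at the earlier
#'   of the drawn duration and the time the target is reached.
#' @return an object of class `motility_parameters`.
#' @export
motility_parameters <- function(mean_run_time = 0.6, mean_tumble_time = 0.4,
                                run_speed_median = 15.1, run_speed_shape = 0.366,
                                tumble_angle_model = tumble_uniform(),
                                reversal_probability = 0,
                                active_tumble_rate = NULL) {
  stopifnot(mean_run_time > 0, mean_tumble_time > 0,
            run_speed_median >= 0, run_speed_shape >= 0,
            inherits(tumble_angle_model, "tumble_model"),
            reversal_probability >= 0, reversal_probability <= 1,
            is.null(active_tumble_rate) || active_tumble_rate >= 0)
  structure(list(mean_run_time = mean_run_time,
                 mean_tumble_time = mean_tumble_time,
                 run_speed_median = run_speed_median,
                 run_speed_shape = run_speed_shape,
                 tumble_angle_model = tumble_angle_model,
                 reversal_probability = reversal_probability,
                 active_tumble_rate = active_tumble_rate),
            class = "motility_parameters")
}

#' Simulation configuration
#'
#' @param frame_rate output sampling rate in Hz (default 30, the video
#'   frame rate).
#' @param duration track duration in s.
#' @param oversampling internal integration steps per output frame; the
#'   internal step is 1/(frame_rate * oversampling).
#' @param arena side of the square arena in um (used for initial positions
#'   and rendering).
#' @param n_motile,n_nonmotile population sizes for [simulate_population()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(frame_rate = 30, duration = 10, oversampling = 10,
                       arena = 242, n_motile = 10, n_nonmotile = 10) {
  stopifnot(frame_rate > 0, duration > 0, oversampling >= 1,
            arena > 0, n_motile >= 0, n_nonmotile >= 0)
  structure(list(frame_rate = frame_rate, duration = duration,
                 oversampling = as.integer(oversampling), arena = arena,
                 n_motile = n_motile, n_nonmotile = n_nonmotile),
            class = "sim_config")
}

#' Build a trajectory object
#'
#' @param frame integer frame indices (0-based).
#' @param time_s,x_um,y_um,orientation_rad,length_um,width_um per-frame data.
#' @param track_id track identifier.
#' @param frame_rate sampling rate in Hz.
#' @param orientation `"directional"` if the orientation is a full swimming
#'   direction in `[0, 2pi)`, `"axial"` if it is a body-axis angle modulo pi.
#' @return a data frame of class `trajectory`.
#' @export
trajectory <- function(frame, time_s, x_um, y_um, orientation_rad,
                       length_um, width_um, track_id = 1L,
                       frame_rate = 30, orientation = c("directional", "axial")) {
  orientation <- match.arg(orientation)
  df <- data.frame(frame = as.integer(frame), time_s = time_s,
                   x_um = x_um, y_um = y_um,
                   orientation_rad = orientation_rad,
                   length_um = length_um, width_um = width_um)
  structure(df, track_id = track_id, frame_rate = frame_rate,
            orientation = orientation,
            class = c("trajectory", "data.frame"))
}

#' Median cell geometry of a track
#'
#' Frame-wise median length and width, the per-track geometry used for all
#' per-cell Brownian expectations.
#' @param traj a [trajectory()].
#' @return an [ellipsoid_geometry()].
#' @export
track_geometry <- function(traj) {
  L <- stats::median(traj$length_um)
  W <- stats::median(traj$width_um)
  ellipsoid_geometry(max(L, W), min(L, W))
}

#' Simulate one run-and-tumble trajectory
#'
#' Runs translate the cell at a per-run lognormal speed along its current
#' orientation; tumbles hold the speed at zero and rotate the body at a
#' constant rate towards a drawn target angle (by default the rate that
#' completes the angle within the tumble's drawn exponential duration; see
#' [motility_parameters()] for the fixed-rate variant). In both phases the
#' position receives anisotropic translational Brownian steps (applied in
#' the body frame with the major/minor-axis diffusivities, then rotated to
#' the lab frame) and the orientation diffuses with the rotational
#' diffusivity of the spheroid. With probability `reversal_probability` a
#' new run starts with an instantaneous pi flip (opposite pole leading).
#'
#' Integration is Euler-Maruyama at dt = 1/(frame_rate * oversampling);
#' the returned track is the subsampled frame-rate series.
#'
#' @param geom an [ellipsoid_geometry()].
#' @param params a [motility_parameters()].
#' @param cfg a [sim_config()].
#' @param medium a [medium()]; sets the Brownian noise amplitudes.
#' @param brownian set `FALSE` to switch all Brownian noise off (noise-free
#'   kinematics, useful for ground-truth checks).
#' @param track_id identifier stored on the trajectory.
#' @param start optional c(x, y) start position in um; default the arena
#'   centre.
#' @return a list with elements `trajectory` (a [trajectory()]) and `truth`
#'   (per-frame phase labels, tumble events with true angles, drawn and
#'   realized phase durations, the generating geometry and parameters).
#' @export
simulate_trajectory <- function(geom, params, cfg, medium, brownian = TRUE,
                                track_id = 1L, start = NULL) {
  stopifnot(inherits(geom, "ellipsoid_geometry"),
            inherits(params, "motility_parameters"),
            inherits(cfg, "sim_config"))
  fr <- cfg$frame_rate
  ov <- cfg$oversampling
  dt <- 1 / (fr * ov)
  n_frames <- floor(cfg$duration * fr)
  n_steps <- n_frames * ov
  if (brownian) {
    ds <- diffusivities(geom, medium)
    sig_par <- sqrt(2 * ds$D_t_major * dt)
    sig_perp <- sqrt(2 * ds$D_t_minor * dt)
    sig_r <- sqrt(2 * ds$D_r * dt)
    if (sig_r > 0.5)
      stop("internal time step too coarse: rotational noise per step exceeds 0.5 rad; increase oversampling")
  } else {
    sig_par <- sig_perp <- sig_r <- 0
  }

  # phase schedule: alternating run / tumble covering the whole track
  kind <- character(0); dur <- numeric(0); drawn <- numeric(0)
  speeds <- numeric(0); targets <- numeric(0); reversed <- logical(0)
  total <- 0; k <- "run"
  while (total < cfg$duration) {
    if (k == "run") {
      d <- stats::rexp(1, 1 / params$mean_run_time)
      v <- if (params$run_speed_median <= 0) 0 else
        stats::rlnorm(1, log(params$run_speed_median), params$run_speed_shape)
      rev <- length(kind) > 0 && stats::runif(1) < params$reversal_probability
      kind <- c(kind, "run"); dur <- c(dur, d); drawn <- c(drawn, d)
      speeds <- c(speeds, v); targets <- c(targets, NA_real_)
      reversed <- c(reversed, rev)
      k <- "tumble"
    } else {
      d0 <- stats::rexp(1, 1 / params$mean_tumble_time)
      tgt <- .draw_tumble_angles(params$tumble_angle_model, 1)
      rate <- params$active_tumble_rate
      d <- if (!is.null(rate) && rate > 0) min(d0, abs(tgt) / rate) else d0
      kind <- c(kind, "tumble"); dur <- c(dur, d); drawn <- c(drawn, d0)
      speeds <- c(speeds, 0); targets <- c(targets, tgt)
      reversed <- c(reversed, FALSE)
      k <- "run"
    }
    total <- total + dur[length(dur)]
  }
  # step allocation per phase
  bounds <- pmin(round(cumsum(dur) / dt), n_steps)
  starts <- c(0, bounds[-length(bounds)])
  steps <- pmax(bounds - starts, 0)

  # per-step drift speed, active rotation, phase id
  v_step <- rep(speeds, steps)
  phase_id <- rep(seq_along(kind), steps)
  active <- numeric(n_steps)
  idx0 <- cumsum(c(0, steps))
  for (i in seq_along(kind)) {
    if (steps[i] == 0) next
    ii <- (idx0[i] + 1):(idx0[i] + steps[i])
    if (kind[i] == "tumble") {
      rate <- params$active_tumble_rate
      if (is.null(rate)) {
        # complete the drawn angle at constant rate over the phase
        active[ii] <- targets[i] / steps[i]
      } else if (rate > 0) {
        rem <- abs(targets[i])
        inc <- pmin(rate * dt,
                    pmax(rem - rate * dt * (seq_len(steps[i]) - 1), 0))
        active[ii] <- sign(targets[i]) * inc
      } else {
        # no active rotation machinery: jump to the target at once
        active[ii[1]] <- targets[i]
      }
    }
    if (kind[i] == "run" && reversed[i]) active[ii[1]] <- active[ii[1]] + pi
  }

  theta0 <- stats::runif(1, 0, 2 * pi)
  dth <- active + if (sig_r > 0) stats::rnorm(n_steps, 0, sig_r) else 0
  theta <- theta0 + cumsum(dth)
  theta_prev <- c(theta0, theta[-n_steps])
  d_par <- v_step * dt + if (sig_par > 0) stats::rnorm(n_steps, 0, sig_par) else 0
  d_perp <- if (sig_perp > 0) stats::rnorm(n_steps, 0, sig_perp) else numeric(n_steps)
  if (is.null(start)) start <- c(cfg$arena / 2, cfg$arena / 2)
  x <- start[1] + cumsum(d_par * cos(theta_prev) - d_perp * sin(theta_prev))
  y <- start[2] + cumsum(d_par * sin(theta_prev) + d_perp * cos(theta_prev))

  out_idx <- seq_len(n_frames) * ov
  frames <- 0:n_frames
  xf <- c(start[1], x[out_idx]); yf <- c(start[2], y[out_idx])
  thf <- wrap_2pi(c(theta0, theta[out_idx]))
  phase_f <- c(kind[phase_id[1]], kind[phase_id[out_idx]])

  traj <- trajectory(frames, frames / fr, xf, yf, thf,
                     rep(geom$length, n_frames + 1), rep(geom$width, n_frames + 1),
                     track_id = track_id, frame_rate = fr,
                     orientation = "directional")
  # an event is a realized tumble whose following run also starts within
  # the track (a reversal flip happens at that run's first step)
  tumbles <- which(kind == "tumble" & steps > 0)
  tumbles <- tumbles[tumbles < length(kind) & steps[pmin(tumbles + 1L, length(steps))] > 0]
  events <- data.frame(
    t_start = starts[tumbles] * dt, t_end = bounds[tumbles] * dt,
    target_angle = targets[tumbles],
    true_angle = wrap_pi(targets[tumbles] +
                           ifelse(c(reversed, FALSE)[tumbles + 1], pi, 0)))
  truth <- list(phase = phase_f, events = events,
                run_durations = dur[kind == "run"],
                tumble_durations = dur[kind == "tumble"],
                drawn_run_durations = drawn[kind == "run"],
                drawn_tumble_durations = drawn[kind == "tumble"],
                run_speeds = speeds[kind == "run"],
                geometry = geom, params = params)
  list(trajectory = traj, truth = truth)
}

#' Simulate a population of non-motile (purely Brownian) cells
#'
#' The passive control: anisotropic translational plus rotational Brownian
#' motion only. Because pure Brownian increments are exactly Gaussian at any
#' step, integration happens directly at the output frame rate.
#'
#' @param n number of cells.
#' @param geoms a single [ellipsoid_geometry()] or a list of them, recycled
#'   over cells.
#' @param cfg a [sim_config()].
#' @param medium a [medium()].
#' @return a list of [trajectory()] objects (orientation `"directional"`,
#'   the true body-axis direction).
#' @export
simulate_brownian_population <- function(n, geoms, cfg, medium) {
  stopifnot(n >= 1, inherits(cfg, "sim_config"))
  if (inherits(geoms, "ellipsoid_geometry")) geoms <- list(geoms)
  fr <- cfg$frame_rate
  dt <- 1 / fr
  n_frames <- floor(cfg$duration * fr)
  lapply(seq_len(n), function(i) {
    g <- geoms[[(i - 1L) %% length(geoms) + 1L]]
    ds <- diffusivities(g, medium)
    sig_par <- sqrt(2 * ds$D_t_major * dt)
    sig_perp <- sqrt(2 * ds$D_t_minor * dt)
    sig_r <- sqrt(2 * ds$D_r * dt)
    theta0 <- stats::runif(1, 0, 2 * pi)
    theta <- theta0 + cumsum(stats::rnorm(n_frames, 0, sig_r))
    theta_prev <- c(theta0, theta[-n_frames])
    d_par <- stats::rnorm(n_frames, 0, sig_par)
    d_perp <- stats::rnorm(n_frames, 0, sig_perp)
    x0 <- stats::runif(1, 0, cfg$arena); y0 <- stats::runif(1, 0, cfg$arena)
    trajectory(0:n_frames, (0:n_frames) / fr,
               c(x0, x0 + cumsum(d_par * cos(theta_prev) - d_perp * sin(theta_prev))),
               c(y0, y0 + cumsum(d_par * sin(theta_prev) + d_perp * cos(theta_prev))),
               wrap_2pi(c(theta0, theta)),
               rep(g$length, n_frames + 1), rep(g$width, n_frames + 1),
               track_id = i, frame_rate = fr, orientation = "directional")
  })
}

#' Simulate a mixed population of motile and non-motile cells
#'
#' @param geoms geometry or list of geometries, recycled.
#' @param params a [motility_parameters()] for the motile fraction.
#' @param cfg a [sim_config()]; `n_motile` and `n_nonmotile` set the mix.
#' @param medium a [medium()].
#' @return list with `trajectories` (motile first), `truth` (per motile
#'   track) and the logical vector `motile`.
#' @export
simulate_population <- function(geoms, params, cfg, medium) {
  if (inherits(geoms, "ellipsoid_geometry")) geoms <- list(geoms)
  mot <- lapply(seq_len(cfg$n_motile), function(i) {
    g <- geoms[[(i - 1L) %% length(geoms) + 1L]]
    simulate_trajectory(g, params, cfg, medium, track_id = i,
                        start = c(stats::runif(1, 0, cfg$arena),
                                  stats::runif(1, 0, cfg$arena)))
  })
  non <- if (cfg$n_nonmotile > 0)
    simulate_brownian_population(cfg$n_nonmotile, geoms, cfg, medium) else list()
  non <- lapply(seq_along(non), function(i) {
    attr(non[[i]], "track_id") <- cfg$n_motile + i
    non[[i]]
  })
  list(trajectories = c(lapply(mot, `[[`, "trajectory"), non),
       truth = lapply(mot, `[[`, "truth"),
       motile = rep(c(TRUE, FALSE), c(cfg$n_motile, length(non))))
}
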