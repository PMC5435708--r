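# detection linking, smoothing and orientation resolution

# minimal synthetic detections with square masks, for linker unit tests
square_detection <- function(frame, cx_px, cy_px, dims = c(60, 60), half = 2L) {
  rows <- (cy_px - half):(cy_px + half)
  cols <- (cx_px - half):(cx_px + half)
  idx <- as.integer(outer(rows, (cols - 1L) * dims[1], "+"))
  df <- data.frame(frame = frame, particle = 1L,
                   x_um = cx_px / 2.75, y_um = cy_px / 2.75,
                   area_um2 = length(idx) / 2.75^2,
                   length_um = 2, width_um = 0.7, orientation_rad = 0)
  df$pixels <- list(idx)
  df
}

bind_detections <- function(lst, dims = c(60, 60)) {
  out <- do.call(rbind, lst)
  attr(out, "dims") <- dims
  out
}

test_that("a single moving cell yields one unbroken track; short tracks are dropped", {
  det <- bind_detections(lapply(0:70, function(f) square_detection(f, 10 + f %/% 3, 30)))
  trks <- link_tracks(det, frame_rate = 30, min_duration = 2)
  expect_equal(length(trks), 1)
  expect_equal(nrow(trks[[1]]), 71)
  # 1.9 s (58 frames) is below the 2 s cutoff, 61 frames passes
  det58 <- bind_detections(lapply(0:57, function(f) square_detection(f, 10, 30)))
  expect_equal(length(link_tracks(det58, 30, 2)), 0)
  det61 <- bind_detections(lapply(0:60, function(f) square_detection(f, 10, 30)))
  expect_equal(length(link_tracks(det61, 30, 2)), 1)
})

test_that("crossing tracks are split at the merge frame", {
  # two cells approach, merge into one detection at frame 10, separate after
  lst <- list()
  for (f in 0:9) {
    lst <- c(lst, list(square_detection(f, 10 + 2 * f, 30),
                       square_detection(f, 50 - 2 * f, 30)))
  }
  lst <- c(lst, list(square_detection(10L, 30, 30)))  # merged blob
  for (f in 11:20) {
    lst <- c(lst, list(square_detection(f, 30 + 2 * (f - 10), 30),
                       square_detection(f, 30 - 2 * (f - 10), 30)))
  }
  trks <- link_tracks(bind_detections(lst), frame_rate = 30, min_duration = 0)
  expect_gte(length(trks), 4)
  spans_crossing <- vapply(trks, function(tr) any(tr$frame < 10) && any(tr$frame > 10),
                           logical(1))
  expect_false(any(spans_crossing))
})

test_that("centroid linking is available as a maskless fallback", {
  det <- bind_detections(lapply(0:70, function(f) square_detection(f, 10 + f %/% 3, 30)))
  det$pixels <- NULL
  trks <- link_tracks(det, frame_rate = 30, min_duration = 2, method = "centroid")
  expect_equal(length(trks), 1)
  expect_equal(nrow(trks[[1]]), 71)
})

test_that("rendered simulator output round-trips through detection and linking", {
  set.seed(19)
  cfg <- sim_config(duration = 2.5, arena = 70, oversampling = 10)
  p <- motility_parameters(mean_run_time = 5, run_speed_median = 8,
                           run_speed_shape = 0)
  sims <- list(
    simulate_trajectory(ellipsoid_geometry(5, 0.7), p, cfg, m33,
                        track_id = 1L, start = c(22, 22)),
    simulate_trajectory(ellipsoid_geometry(8, 0.7), p, cfg, m33,
                        track_id = 2L, start = c(48, 48)))
  st <- render_frames(lapply(sims, `[[`, "trajectory"), cfg, noise_sd = 1)
  sub <- subtract_background(st)
  det <- detect_stack(sub, detection_config())
  trks <- link_tracks(det, frame_rate = 30, min_duration = 2)
  expect_equal(length(trks), 2)
  med_lens <- sort(vapply(trks, function(tr) median(tr$length_um), 0))
  expect_lt(abs(med_lens[1] - 5), 0.4)
  expect_lt(abs(med_lens[2] - 8), 0.4)
})

test_that("smoothing preserves constants, reduces white-noise variance ~5-fold, and respects wrap-around", {
  const <- trajectory(0:49, (0:49) / 30, rep(3, 50), rep(4, 50), rep(1, 50),
                      rep(2, 50), rep(0.7, 50), frame_rate = 30)
  sm <- smooth_track(const, 5L)
  expect_equal(sm$x_um, rep(3, 50))
  expect_equal(sm$orientation_rad, rep(1, 50), tolerance = 1e-9)
  set.seed(23)
  noisy <- trajectory(0:1999, (0:1999) / 30, rnorm(2000), rnorm(2000),
                      rep(0, 2000), rep(2, 2000), rep(0.7, 2000), frame_rate = 30)
  smn <- smooth_track(noisy, 5L)
  inner <- 3:1998
  ratio <- var(noisy$x_um[inner]) / var(smn$x_um[inner])
  expect_equal(ratio, 5, tolerance = 0.25)
  # axial angles straddling the +/- pi/2 wrap stay near the axis
  th <- wrap_pi(pi / 2 + rnorm(50, 0, 0.03))
  th <- ifelse(th > pi / 2, th - pi, th)  # axial convention [-pi/2, pi/2)
  wrapped <- trajectory(0:49, (0:49) / 30, rep(0, 50), rep(0, 50), th,
                        rep(5, 50), rep(0.7, 50), frame_rate = 30,
                        orientation = "axial")
  smw <- smooth_track(wrapped, 5L)
  expect_true(all(abs(abs(smw$orientation_rad) - pi / 2) < 0.1))
  expect_error(smooth_track(const, 4L))
  expect_error(smooth_track(const, 51L), "window")
})

test_that("orientation resolution picks the head from the motion direction", {
  # steady 45-degree translation with an axial +/- pi ambiguity
  n <- 30
  tr <- trajectory(0:(n - 1), (0:(n - 1)) / 30,
                   (0:(n - 1)) * 0.3, (0:(n - 1)) * 0.3,
                   rep(pi / 4, n), rep(5, n), rep(0.7, n),
                   frame_rate = 30, orientation = "axial")
  res <- resolve_orientation(tr)
  expect_true(all(abs(wrap_pi(res$orientation_rad - pi / 4)) < 1e-6))
  # same axis, opposite motion: resolved to the opposite head
  tr2 <- trajectory(0:(n - 1), (0:(n - 1)) / 30,
                    -(0:(n - 1)) * 0.3, -(0:(n - 1)) * 0.3,
                    rep(pi / 4, n), rep(5, n), rep(0.7, n),
                    frame_rate = 30, orientation = "axial")
  res2 <- resolve_orientation(tr2)
  expect_true(all(abs(wrap_pi(res2$orientation_rad - 5 * pi / 4)) < 1e-6))
})

test_that("a reversal flips the resolved orientation of a short cell by ~pi in one step", {
  n <- 21; v <- 0.4
  x <- c(seq(0, by = v, length.out = 11), seq(v * 10 - v, by = -v, length.out = 10))
  tr <- trajectory(0:(n - 1), (0:(n - 1)) / 30, x, rep(0, n),
                   rep(0, n), rep(1.7, n), rep(0.7, n),
                   frame_rate = 30, orientation = "axial")
  res <- resolve_orientation(tr)
  th <- res$orientation_rad
  expect_lt(abs(wrap_pi(th[3] - 0)), 0.1)
  expect_lt(abs(wrap_pi(th[18] - pi)), 0.1)
  jumps <- abs(wrap_pi(diff(th)))
  expect_gt(max(jumps), pi - 0.2)
})

test_that("resolved orientations track simulator truth within 5 degrees RMS for an elongated runner", {
  set.seed(29)
  cfg <- sim_config(duration = 4, arena = 200)
  p <- motility_parameters(mean_run_time = 100, run_speed_median = 12,
                           run_speed_shape = 0)
  sim <- simulate_trajectory(ellipsoid_geometry(3.5, 0.7), p, cfg, m33)
  truth <- sim$trajectory$orientation_rad
  obs <- sim$trajectory
  obs$orientation_rad <- wrap_pi(truth) # collapse to axial ambiguity
  obs$orientation_rad <- ifelse(obs$orientation_rad >= pi / 2,
                                obs$orientation_rad - pi,
                                ifelse(obs$orientation_rad < -pi / 2,
                                       obs$orientation_rad + pi,
                                       obs$orientation_rad))
  attr(obs, "orientation") <- "axial"
  res <- resolve_orientation(obs)
  rms <- sqrt(mean(wrap_pi(res$orientation_rad - truth)^2))
  expect_lt(rms, 5 * pi / 180)
})

test_that("track CSV writing and reading round-trips the schema", {
  set.seed(31)
  sim <- simulate_trajectory(g_normal, motility_parameters(),
                             sim_config(duration = 2.5, arena = 60), m33)
  path <- tempfile(fileext = ".csv")
  write_tracks(sim$trajectory, path)
  back <- read_tracks(path)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$x_um, sim$trajectory$x_um, tolerance = 1e-9)
  expect_equal(attr(back[[1]], "frame_rate"), 30)
})
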