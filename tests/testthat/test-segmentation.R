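# motile/non-motile discrimination and run/tumble segmentation

thr_normal <- brownian_thresholds(g_normal, m33)

test_that("Brownian thresholds follow the closed-form quantile expressions", {
  # frozen closed-form evaluation for the normal-size cell at t = 0.17 s
  expect_equal(thr_normal$speed_threshold, 7.140225, tolerance = 1e-4)
  expect_equal(thr_normal$angular_velocity_threshold, 9.513255, tolerance = 1e-4)
  expect_equal(thr_normal$sigma_t, sqrt(2 * 0.65310 * 0.17), tolerance = 1e-4)
  # thresholds scale as 1/sqrt(t)
  thr4 <- brownian_thresholds(g_normal, m33, window = 4 * 0.17)
  expect_equal(thr_normal$speed_threshold / thr4$speed_threshold, 2, tolerance = 1e-9)
  # longer cells diffuse less: both thresholds strictly decrease with length
  sp <- sapply(c(1.7, 3, 6, 12), function(L)
    brownian_thresholds(ellipsoid_geometry(L, 0.7), m33)$speed_threshold)
  av <- sapply(c(1.7, 3, 6, 12), function(L)
    brownian_thresholds(ellipsoid_geometry(L, 0.7), m33)$angular_velocity_threshold)
  expect_true(all(diff(sp) < 0) && all(diff(av) < 0))
  # signed vs magnitude tails differ by the quantile ratio
  thr_s <- brownian_thresholds(g_normal, m33, tail = "signed")
  expect_equal(thr_s$speed_threshold / thr_normal$speed_threshold,
               qnorm(0.99) / qnorm(0.995), tolerance = 1e-9)
  expect_error(brownian_thresholds(g_normal, m33, window = 0), "window")
})

test_that("motility classification separates swimmers from Brownian particles", {
  set.seed(201)
  # a zero-displacement track is non-motile
  still <- trajectory(0:90, (0:90) / 30, rep(1, 91), rep(1, 91), rep(0.3, 91),
                      rep(1.7, 91), rep(0.7, 91), frame_rate = 30)
  expect_equal(as.character(classify_motile(still, m33)), "nonmotile")
  # a 16 um/s runner is detected with overwhelming power
  p <- motility_parameters(mean_run_time = 100, run_speed_shape = 0)
  cfg <- sim_config(duration = 2.5, arena = 1e4)
  runners <- sapply(1:30, function(i)
    classify_motile(simulate_trajectory(g_normal, p, cfg, m33)$trajectory, m33))
  expect_true(all(runners == "motile"))
  expect_error(classify_motile(still[1:10, ], m33))
  bad <- still; bad$orientation_rad[5] <- NA
  expect_error(classify_motile(bad, m33), "orientation")
})

test_that("a noise-free runner yields one run segment flagged incomplete at both ends", {
  set.seed(207)
  p <- motility_parameters(mean_run_time = 1e6, run_speed_shape = 0)
  s <- simulate_trajectory(g_normal, p, sim_config(duration = 4, arena = 1e3),
                           m33, brownian = FALSE)
  ss <- segment_track(s$trajectory, thr_normal)
  expect_equal(nrow(ss$segments), 1)
  expect_equal(ss$segments$kind, "run")
  expect_false(ss$segments$complete)
  expect_error(segment_track(s$trajectory[1:4, ], thr_normal), "window")
})

test_that("segmentation labels agree with simulator ground truth and recover uniform tumbling", {
  set.seed(211)
  cfg <- sim_config(duration = 25, arena = 1e5)
  agree <- c(); angles <- c(); segs <- list()
  for (i in 1:12) {
    s <- simulate_trajectory(g_normal, motility_parameters(), cfg, m33)
    ss <- segment_track(s$trajectory, thr_normal)
    segs[[i]] <- ss
    agree <- c(agree, mean(ss$labels == s$truth$phase))
    angles <- c(angles, ss$segments$angle[!is.na(ss$segments$angle)])
  }
  expect_gte(mean(agree), 0.85)
  expect_lt(abs(mean(cos(angles))), 0.1)
  sm <- summarize_motility(segs)
  expect_equal(sm$run_time_mean, 0.6, tolerance = 0.25)
  expect_equal(sm$run_speed_mean, 16.14, tolerance = 0.15)
})

test_that("a purely Brownian track forced through segmentation is almost all tumble", {
  set.seed(213)
  cfg <- sim_config(duration = 10, arena = 1e4)
  pop <- simulate_brownian_population(50, g_normal, cfg, m33)
  frac_run <- mean(unlist(lapply(pop, function(tr)
    segment_track(tr, thr_normal)$labels == "run")))
  expect_lte(frac_run, 0.02)
})

test_that("segmentation is invariant under global translation and rotation", {
  set.seed(217)
  s <- simulate_trajectory(g_normal, motility_parameters(),
                           sim_config(duration = 10, arena = 1e4), m33)
  tr <- s$trajectory
  ref <- segment_track(tr, thr_normal)
  rot <- 1.1
  tr2 <- tr
  tr2$x_um <- 50 + cos(rot) * tr$x_um - sin(rot) * tr$y_um
  tr2$y_um <- -20 + sin(rot) * tr$x_um + cos(rot) * tr$y_um
  tr2$orientation_rad <- wrap_2pi(tr$orientation_rad + rot)
  out <- segment_track(tr2, thr_normal)
  expect_identical(out$labels, ref$labels)
  expect_equal(out$segments$angle, ref$segments$angle, tolerance = 1e-9)
})

test_that("parameter recovery holds across the length x run-time grid", {
  set.seed(219)
  for (L in c(1.7, 5, 10)) {
    for (mrt in c(0.4, 0.6, 1.0)) {
      g <- ellipsoid_geometry(L, 0.7)
      thr <- brownian_thresholds(g, m33)
      cfg <- sim_config(duration = 15, arena = 1e5)
      p <- motility_parameters(mean_run_time = mrt)
      segs <- lapply(1:16, function(i)
        segment_track(simulate_trajectory(g, p, cfg, m33)$trajectory, thr))
      sm <- summarize_motility(segs)
      # run times are biased short by threshold-crossing noise (hence the
      # wider band); speeds recover tightly
      expect_lt(abs(sm$run_time_mean - mrt) / mrt, 0.25)
      expect_lt(abs(sm$run_speed_mean - 16.14) / 16.14, 0.15)
    }
  }
})

fake_segments <- function(run_times, run_speeds, tumble_times, angles) {
  n_r <- length(run_times); n_t <- length(tumble_times)
  seg <- data.frame(
    kind = c(rep("run", n_r), rep("tumble", n_t)),
    start_frame = 0L, end_frame = 0L, t_start = 0, t_end = 0,
    duration = c(run_times, tumble_times),
    complete = TRUE,
    mean_speed = c(run_speeds, rep(NA_real_, n_t)),
    angle = c(rep(NA_real_, n_r), angles))
  structure(list(segments = seg, labels = character(0), track_id = 1L,
                 window = 0.17, thresholds = NULL), class = "segment_set")
}

test_that("motility summaries reproduce the analytic moments of crafted segments", {
  # all tumbles at 90 degrees: mean cos and mean |cos| both zero
  s90 <- fake_segments(rexp(50, 1 / 0.6), rlnorm(50, log(15), 0.3),
                       rep(0.4, 50), rep(pi / 2, 50))
  sm <- summarize_motility(s90)
  expect_equal(sm$mean_cos, 0, tolerance = 1e-9)
  expect_equal(sm$mean_abs_cos, 0, tolerance = 1e-9)
  # uniform angles: mean |cos| near 2/pi, mean cos near 0
  set.seed(223)
  su <- fake_segments(rexp(100, 2), rlnorm(100, log(15), 0.3),
                      rep(0.3, 1e4), runif(1e4, -pi, pi))
  smu <- summarize_motility(su)
  expect_equal(smu$mean_abs_cos, 2 / pi, tolerance = 0.02)
  expect_lt(abs(smu$mean_cos), 0.03)
  expect_lte(abs(smu$mean_cos), smu$mean_abs_cos)
  # exponential rate MLE within 2 standard errors at n = 5000
  durs <- rexp(5000, 1 / 0.6)
  se <- fake_segments(durs, rep(15, 5000), numeric(0), numeric(0))
  sme <- summarize_motility(se)
  expect_equal(sme$run_time_rate, 1 / mean(durs), tolerance = 1e-9)
  expect_lt(abs(sme$run_time_rate - 1 / 0.6), 2 * sme$run_time_rate / sqrt(5000))
  expect_error(summarize_motility(fake_segments(numeric(0), numeric(0),
                                                numeric(0), numeric(0))))
})
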