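# Population-level dispersal: mean-square angular deviation (MSAD) time
# constants, bacterial diffusivity by run-and-tumble statistics and by
# Taylor's dispersion equation, and logarithmic size-class binning.

#' Time constant from mean-square angular deviations
#'
#' During a run the orientation of a passive spheroid diffuses so that
#' <phi^2>(t) = 2 D_r t. Orientation differences over a range of lags are
#' pooled over all in-run pairs, the least-squares slope of <phi^2> versus
#' lag gives D_r (slope/2), and the time constant tau = 1/(2 D_r) is the
#' time for the RMS deviation to reach one radian. Confidence bounds come
#' from the regression slope.
#'
#' @param runs a list whose elements are either [trajectory()] objects or
#'   plain numeric orientation series (radians), one per run.
#' @param frame_rate sampling rate in Hz.
#' @param lag_span range of lags in seconds (default 0.03 to 0.33, the
#'   span that stays within the linear regime).
#' @param min_runs minimum number of runs required (default 30).
#' @return an object of class `msad_fit` with the lag grid, the pooled
#'   `msad`, `D_r`, `tau`, `tau_ci` and an `unbounded` flag (slope <= 0).
#' @export
msad_time_constant <- function(runs, frame_rate = 30,
                               lag_span = c(0.03, 0.33), min_runs = 30) {
  if (!is.list(runs)) stop("runs must be a list of trajectories or orientation series")
  if (length(runs) < min_runs)
    stop(sprintf("need at least %d runs for a stable MSAD fit", min_runs))
  phis <- lapply(runs, function(r) {
    th <- if (inherits(r, "trajectory")) r$orientation_rad else as.numeric(r)
    unwrap_angle(th)
  })
  lags <- max(1L, ceiling(lag_span[1] * frame_rate)):floor(lag_span[2] * frame_rate)
  if (length(lags) < 2L) stop("lag span too narrow at this frame rate")
  msad <- numeric(length(lags))
  npairs <- integer(length(lags))
  for (k in seq_along(lags)) {
    L <- lags[k]
    sq <- unlist(lapply(phis, function(p) {
      n <- length(p)
      if (n <= L) return(numeric(0))
      (p[(L + 1):n] - p[seq_len(n - L)])^2
    }))
    msad[k] <- mean(sq)
    npairs[k] <- length(sq)
  }
  if (any(npairs == 0)) stop("runs too short for the requested lag span")
  lag_s <- lags / frame_rate
  fit <- stats::lm(msad ~ lag_s)
  slope <- unname(stats::coef(fit)[2])
  ci <- tryCatch(stats::confint(fit)[2, ], error = function(e) c(NA, NA))
  unbounded <- !is.finite(slope) || slope <= 0
  D_r <- if (unbounded) 0 else slope / 2
  tau <- if (unbounded) Inf else 1 / (2 * D_r)
  tau_ci <- sort(1 / pmax(ci, 0))  # slope CI -> tau CI (upper slope, lower tau)
  structure(list(lag_s = lag_s, msad = msad, n_pairs = npairs,
                 D_r = D_r, tau = tau, tau_ci = unname(tau_ci),
                 unbounded = unbounded, fit = fit),
            class = "msad_fit")
}

#' @export
print.msad_fit <- function(x, ...) {
  if (x$unbounded) {
    cat("MSAD fit: slope <= 0; orientation loss unbounded (tau = Inf)\n")
  } else {
    cat(sprintf("MSAD fit over %d lags: D_r = %.4g rad^2/s, tau = %.3g s (95%% CI %.3g-%.3g)\n",
                length(x$lag_s), x$D_r, x$tau, x$tau_ci[1], x$tau_ci[2]))
  }
  invisible(x)
}

#' @export
coef.msad_fit <- function(object, ...) c(D_r = object$D_r, tau = object$tau)

#' Bacterial diffusivity from run-and-tumble statistics
#'
#' D_b = v^2 tau_run / (n (1 - alpha)) with v the mean run speed, tau_run
#' the mean run duration, n the number of dimensions and alpha the mean
#' cosine of the angle between successive runs (directional persistence
#' inflates dispersal as alpha approaches 1).
#'
#' @param summary a [summarize_motility()] result, or a list with fields
#'   `run_speed_mean`, `run_time_mean`, `mean_cos`.
#' @param n_dims number of dimensions (default 2, the tracked plane).
#' @return an object of class `diffusivity_estimate` (um^2/s).
#' @examples
#' s <- list(run_speed_mean = 16.1, run_time_mean = 0.6, mean_cos = 0)
#' diffusivity_run_tumble(s)  # 77.8 um^2/s
#' @export
diffusivity_run_tumble <- function(summary, n_dims = 2) {
  v <- summary$run_speed_mean
  tau <- summary$run_time_mean
  alpha <- summary$mean_cos
  stopifnot(is.finite(v), is.finite(tau), is.finite(alpha), v >= 0, tau > 0)
  if (alpha >= 1) stop("mean cosine of 1 gives unbounded persistence; D_b undefined")
  structure(list(method = "run_tumble",
                 D_b = v^2 * tau / (n_dims * (1 - alpha)),
                 v = v, tau = tau, alpha = alpha, n_dims = n_dims,
                 se = NA_real_),
            class = "diffusivity_estimate")
}

#' Fit Taylor's dispersion equation to RMSD data
#'
#' Taylor's equation for a correlated random walk,
#' RMSD(t) = sqrt(2 v^2 rho (t - rho (1 - exp(-t/rho)))), interpolates the
#' ballistic short-time limit RMSD ~ v t and the diffusive long-time limit
#' RMSD ~ sqrt(2 v^2 rho t). Nonlinear least squares estimates the speed v
#' and the correlation time rho.
#'
#' @param t_s lag times in seconds.
#' @param rmsd root-mean-square net displacements in um.
#' @return list with `v`, `rho`, their standard errors and the `nls` fit.
#' @export
fit_taylor <- function(t_s, rmsd) {
  stopifnot(length(t_s) == length(rmsd), length(t_s) >= 4)
  v0 <- rmsd[which.min(t_s)] / min(t_s)
  fit <- tryCatch(
    minpack.lm::nlsLM(rmsd ~ sqrt(2 * v^2 * rho * (t_s - rho * (1 - exp(-t_s / rho)))),
                      start = list(v = max(v0, 1e-3), rho = max(stats::median(t_s) / 2, 1e-3)),
                      lower = c(1e-9, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Taylor fit failed to converge: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(NA, NA))
  list(v = unname(cf["v"]), rho = unname(cf["rho"]),
       v_se = unname(se[1]), rho_se = unname(se[2]), fit = fit)
}

#' Bacterial diffusivity from Taylor's dispersion equation
#'
#' Computes RMSD(t) = sqrt(mean_i [(x_i(t)-x_i(0))^2 + (y_i(t)-y_i(0))^2])
#' over all tracks truncated to a common horizon, fits Taylor's equation
#' for (v, rho) on a log-spaced lag grid, and reports D_b = v^2 rho / n.
#' This route uses no run/tumble statistics at all, so it cross-validates
#' the run-and-tumble estimator.
#'
#' @param trajs list of [trajectory()] objects, each at least `horizon`
#'   seconds long.
#' @param horizon common evaluation horizon in seconds (default 2).
#' @param n_lags number of log-spaced lags (default 25).
#' @param n_dims number of dimensions (default 2).
#' @param min_tracks minimum number of tracks (default 50).
#' @return an object of class `diffusivity_estimate` with `v`, `rho`,
#'   `D_b`, a delta-method `se`, and the underlying fit.
#' @export
diffusivity_taylor <- function(trajs, horizon = 2, n_lags = 25, n_dims = 2,
                               min_tracks = 50) {
  stopifnot(is.list(trajs))
  fr <- attr(trajs[[1]], "frame_rate")
  H <- floor(horizon * fr)
  keep <- Filter(function(tr) nrow(tr) > H, trajs)
  if (length(keep) < min_tracks)
    stop(sprintf("need at least %d tracks of %g s for the Taylor fit", min_tracks, horizon))
  lags <- sort(unique(pmax(1L, round(exp(seq(log(1), log(H), length.out = n_lags))))))
  X <- vapply(keep, function(tr) tr$x_um[1 + c(0L, lags)], numeric(length(lags) + 1L))
  Y <- vapply(keep, function(tr) tr$y_um[1 + c(0L, lags)], numeric(length(lags) + 1L))
  dx <- X[-1, , drop = FALSE] - rep(X[1, ], each = length(lags))
  dy <- Y[-1, , drop = FALSE] - rep(Y[1, ], each = length(lags))
  rmsd <- sqrt(rowMeans(dx^2 + dy^2))
  tf <- fit_taylor(lags / fr, rmsd)
  D_b <- tf$v^2 * tf$rho / n_dims
  se <- if (is.finite(tf$v_se) && is.finite(tf$rho_se)) {
    V <- stats::vcov(tf$fit)
    g <- c(2 * tf$v * tf$rho / n_dims, tf$v^2 / n_dims)
    sqrt(drop(t(g) %*% V %*% g))
  } else NA_real_
  structure(list(method = "taylor", D_b = D_b, v = tf$v, rho = tf$rho,
                 se = se, n_dims = n_dims, n_tracks = length(keep),
                 lag_s = lags / fr, rmsd = rmsd, fit = tf$fit),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  lab <- if (x$method == "taylor") "Taylor dispersion" else "run-and-tumble statistics"
  cat(sprintf("bacterial diffusivity (%s): D_b = %.3g um^2/s", lab, x$D_b))
  if (is.finite(x$se)) cat(sprintf(" +/- %.2g", x$se))
  cat("\n")
  if (x$method == "taylor")
    cat(sprintf("  fitted v = %.3g um/s, correlation time rho = %.3g s (%d tracks)\n",
                x$v, x$rho, x$n_tracks))
  invisible(x)
}

#' Logarithmic size classes
#'
#' Cell lengths in an elongation series are roughly exponentially
#' distributed, so linear bins over-represent the shortest cells; base-2
#' logarithmic bins spread observations far more evenly and refine the
#' short-length range where the swimming parameters change fastest. Bins
#' holding fewer than `min_count` observations are flagged excluded.
#'
#' @param lengths cell lengths in um.
#' @param bins_per_octave bins per doubling of length (default 2).
#' @param min_count minimum observations for a bin to be used (default 100).
#' @return an object of class `size_classing`: `edges`, per-observation
#'   `bin`, per-bin `counts`, `mid` (geometric midpoints) and `excluded`.
#' @export
bin_by_length <- function(lengths, bins_per_octave = 2, min_count = 100) {
  stopifnot(all(is.finite(lengths)), all(lengths > 0), bins_per_octave >= 1)
  lo <- floor(log2(min(lengths)) * bins_per_octave) / bins_per_octave
  hi <- ceiling(log2(max(lengths)) * bins_per_octave) / bins_per_octave
  if (hi <= lo) hi <- lo + 1 / bins_per_octave
  edges <- 2^seq(lo, hi, by = 1 / bins_per_octave)
  bin <- findInterval(lengths, edges, rightmost.closed = TRUE)
  bin[bin > length(edges) - 1L] <- length(edges) - 1L
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  structure(list(edges = edges, bin = bin, counts = counts,
                 mid = sqrt(edges[-1] * edges[-length(edges)]),
                 excluded = counts < min_count, min_count = min_count),
            class = "size_classing")
}

#' @export
print.size_classing <- function(x, ...) {
  used <- sum(!x$excluded & x$counts > 0)
  cat(sprintf("size classes: %d bins (%d usable with >= %d observations)\n",
              length(x$counts), used, x$min_count))
  invisible(x)
}
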