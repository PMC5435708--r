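# Forward models linking cell geometry to swimming speed and tumble angle:
# resistive force theory propulsion, power-density vs constant-power scaling,
# the tumble-angle restriction model and small worked-example calculators.

#' Geometry of the flagellar bundle as a single rigid helix
#'
#' @param axial_length axial (end-to-end) length of the helix in um; the
#'   filament contour length is derived from it via the pitch angle.
#' @param pitch helical pitch (axial length per turn) in um.
#' @param amplitude helix radius in um; 0 gives a straight filament.
#' @param thickness filament (bundle) diameter in um.
#' @param rotation_rate bundle rotation rate omega_f in rad/s.
#' @return an object of class `flagellar_bundle`.
#' @examples
#' flagellar_bundle()  # population-average bundle
#' @export
flagellar_bundle <- function(axial_length = 6.0, pitch = 2.34,
                             amplitude = 0.25, thickness = 0.1,
                             rotation_rate = 2 * pi * 131) {
  stopifnot(axial_length > 0, thickness > 0, rotation_rate > 0, amplitude >= 0)
  if (pitch <= 0) stop("helix pitch must be positive")
  structure(list(axial_length = axial_length, pitch = pitch,
                 amplitude = amplitude, thickness = thickness,
                 rotation_rate = rotation_rate),
            class = "flagellar_bundle")
}

#' Propulsion matrix of a rotating helical bundle
#'
#' Resistive force theory for a rigid helix: with pitch angle psi
#' (tan psi = 2 pi R / pitch), filament contour length l and drag
#' coefficients per unit length c_t (tangential) and c_n (normal),
#' the axial drag is A = l (c_t cos^2 psi + c_n sin^2 psi) and the
#' thrust coupling B = l R sin psi cos psi (c_n - c_t). A straight
#' filament (R = 0) produces no thrust (B = 0).
#'
#' @param flag a [flagellar_bundle()].
#' @param medium a [medium()].
#' @param coefficients drag-coefficient variant: Lighthill's slender-body
#'   coefficients with the pitch as reference wavelength (default), or the
#'   classical Gray-Hancock form.
#' @return an object of class `propulsion_matrix` with `A` (N s m^-1),
#'   `B` (N s), and the coefficient ratio `cn_ct`.
#' @examples
#' propulsion_matrix(flagellar_bundle(), medium(306.15, 0.76e-3))
#' @export
propulsion_matrix <- function(flag, medium,
                              coefficients = c("lighthill", "gray-hancock")) {
  stopifnot(inherits(flag, "flagellar_bundle"), inherits(medium, "medium"))
  coefficients <- match.arg(coefficients)
  eta <- medium$viscosity
  lam <- flag$pitch * 1e-6
  R <- flag$amplitude * 1e-6
  rf <- flag$thickness / 2 * 1e-6
  psi <- atan(2 * pi * R / lam)
  ell <- flag$axial_length * 1e-6 / cos(psi)
  if (coefficients == "lighthill") {
    den <- log(0.18 * lam / rf)
    if (den <= 0) stop("filament too thick for the slender-body coefficients")
    ct <- 2 * pi * eta / den
    cn <- 4 * pi * eta / (den + 0.5)
  } else {
    den <- log(2 * lam / rf)
    ct <- 2 * pi * eta / (den - 0.5)
    cn <- 4 * pi * eta / (den + 0.5)
  }
  structure(list(A = ell * (ct * cos(psi)^2 + cn * sin(psi)^2),
                 B = ell * R * sin(psi) * cos(psi) * (cn - ct),
                 cn_ct = cn / ct, psi = psi, contour_length = ell * 1e6),
            class = "propulsion_matrix")
}

#' @export
print.propulsion_matrix <- function(x, ...) {
  cat(sprintf("propulsion matrix: A = %.4g N s/m, B = %.4g N s (c_n/c_t = %.3f)\n",
              x$A, x$B, x$cn_ct))
  invisible(x)
}

#' Swimming speed from resistive force theory
#'
#' Force balance between bundle thrust and body + bundle drag:
#' v = B omega_f / (f_t + A), with f_t the major-axis translational friction
#' of the cell body. Speed decreases as the cell elongates because f_t grows.
#'
#' @param geom cell body [ellipsoid_geometry()].
#' @param flag a [flagellar_bundle()].
#' @param medium a [medium()].
#' @param coefficients passed to [propulsion_matrix()].
#' @return swimming speed in um/s.
#' @examples
#' rft_speed(ellipsoid_geometry(1.7, 0.7), flagellar_bundle(), medium(306.15, 0.76e-3))
#' @export
rft_speed <- function(geom, flag, medium,
                      coefficients = c("lighthill", "gray-hancock")) {
  pm <- propulsion_matrix(flag, medium, coefficients)
  f_t <- friction_coefficients(geom, medium)$f_t_major
  pm$B * flag$rotation_rate / (f_t + pm$A) * 1e6
}

#' Reference (normal-size) cell for power-scaling models
#'
#' Packages the subscript-n quantities: the geometry, run speed and tumble
#' angular velocity of the normal-size population. The default tumble
#' angular velocity is the deliberately conservative quotient of the mean
#' tumble angle and the mean tumble duration (90 degrees over 0.4 s).
#'
#' @param geometry reference [ellipsoid_geometry()] (default 1.7 x 0.7 um).
#' @param run_speed mean run speed v_n in um/s.
#' @param tumble_angle mean tumble angle in radians.
#' @param tumble_time mean tumble duration in seconds.
#' @return an object of class `reference_cell` with fields `geometry`,
#'   `run_speed`, `tumble_angular_velocity` and `volume` (um^3).
#' @export
reference_cell <- function(geometry = ellipsoid_geometry(1.7, 0.7),
                           run_speed = 16.1,
                           tumble_angle = pi / 2, tumble_time = 0.4) {
  stopifnot(inherits(geometry, "ellipsoid_geometry"),
            run_speed > 0, tumble_angle > 0, tumble_time > 0)
  structure(list(geometry = geometry, run_speed = run_speed,
                 tumble_angular_velocity = tumble_angle / tumble_time,
                 volume = spheroid_volume(geometry)),
            class = "reference_cell")
}

# shared scaling kernel: sqrt(f_ref/f * (V/V_ref)^w) * x_ref, w = 1 for the
# constant-power-density scenario and 0 for constant total power
.power_scale <- function(f_ref, f, V, V_ref, x_ref, mode) {
  w <- switch(mode, power_density = 1, constant_power = 0)
  sqrt(f_ref / f * (V / V_ref)^w * x_ref^2)
}

#' Run speed scaled from a reference cell by a power budget
#'
#' Two bracketing scenarios for how the propulsive power changes with cell
#' volume V under elongation: `power_density` holds P/V fixed
#' (v = sqrt(f_tn/f_t * V/V_n * v_n^2), speed rises with length) and
#' `constant_power` holds P fixed (v = sqrt(f_tn/f_t * v_n^2), speed falls).
#' Any model with power between constant and proportional to V lies between
#' the two curves.
#'
#' @param geom target cell [ellipsoid_geometry()].
#' @param ref a [reference_cell()].
#' @param medium a [medium()].
#' @param mode `"power_density"` or `"constant_power"`.
#' @return predicted run speed in um/s.
#' @export
scaled_speed <- function(geom, ref, medium,
                         mode = c("power_density", "constant_power")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "reference_cell"))
  f <- friction_coefficients(geom, medium)$f_t_major
  f_ref <- friction_coefficients(ref$geometry, medium)$f_t_major
  .power_scale(f_ref, f, spheroid_volume(geom), ref$volume, ref$run_speed, mode)
}

#' Tumble angular velocity scaled from a reference cell
#'
#' The rotational analogue of [scaled_speed()]: omega =
#' sqrt(f_rn/f_r * V/V_n * omega_n^2) when power density is conserved, and
#' without the volume factor at constant power. Because f_r grows much
#' faster than V with length, both scenarios predict increasingly
#' restricted tumbles in elongated cells.
#'
#' @inheritParams scaled_speed
#' @return predicted tumble angular velocity in rad/s.
#' @export
scaled_tumble_angular_velocity <- function(geom, ref, medium,
                                           mode = c("power_density", "constant_power")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ref, "reference_cell"))
  f <- friction_coefficients(geom, medium)$f_r_minor
  f_ref <- friction_coefficients(ref$geometry, medium)$f_r_minor
  .power_scale(f_ref, f, spheroid_volume(geom), ref$volume,
               ref$tumble_angular_velocity, mode)
}

#' Mean |cos| of tumble angles drawn uniformly up to a maximum angle
#'
#' For tumble angles uniform on (0, alpha_m] the mean absolute cosine is
#' (1/alpha_m) integral_0^alpha_m |cos a| da, in closed form
#' sin(alpha_m)/alpha_m for alpha_m <= pi/2 and (2 - sin(alpha_m))/alpha_m
#' beyond. The absolute value makes the statistic insensitive to the
#' swimming direction (180-degree reversals), so it reflects only the
#' restriction to turning; at alpha_m = pi it equals 2/pi, the value for a
#' fully uniform angle distribution.
#'
#' @param alpha_m maximum tumble angle in radians, 0 < alpha_m <= pi.
#' @return mean absolute cosine (dimensionless), vectorized over `alpha_m`.
#' @examples
#' expected_abs_cos_tumble(pi)      # 2/pi, uniform reference line
#' expected_abs_cos_tumble(pi / 6)  # forward-restricted tumbling
#' @export
expected_abs_cos_tumble <- function(alpha_m) {
  if (any(!is.finite(alpha_m)) || any(alpha_m <= 0) || any(alpha_m > pi))
    stop("alpha_m must lie in (0, pi]")
  ifelse(alpha_m <= pi / 2,
         sin(alpha_m) / alpha_m,
         (2 - sin(alpha_m)) / alpha_m)
}

#' Tumble time predicted from cell length
#'
#' Logarithmic regression t = t_n + b log10(l / l_n) anchored at the
#' normal-size cell; the default slope is the least-squares estimate from
#' the elongation series.
#'
#' @param length cell length in um (vectorized).
#' @param t_n tumble time of the normal-size cell in s.
#' @param b regression slope (s per decade of length).
#' @param l_n normal-size cell length in um.
#' @return predicted tumble time in s.
#' @examples
#' predicted_tumble_time(17)  # ten-fold elongation: 0.77 s
#' @export
predicted_tumble_time <- function(length, t_n = 0.4, b = 0.37, l_n = 1.7) {
  stopifnot(all(length > 0), l_n > 0)
  t_n + b * log10(length / l_n)
}

#' Turn angle rescaled between media of different viscosity
#'
#' Equal-rotational-power argument: P_r = f_r omega^2 with f_r proportional
#' to viscosity, so eta_H omega_H^2 = eta_L omega_L^2. A turn of `angle`
#' performed in time t at viscosity eta_H maps to angle * sqrt(eta_H/eta_L)
#' in the same time at eta_L.
#'
#' @param angle turn angle achieved at viscosity `eta_high`, in degrees.
#' @param eta_high,eta_low dynamic viscosities in Pa s.
#' @return the turn angle at `eta_low`, in degrees.
#' @examples
#' viscosity_scaled_turn(68, 2.7e-3, water_viscosity(306.15))  # ~129 degrees
#' @export
viscosity_scaled_turn <- function(angle, eta_high, eta_low) {
  stopifnot(eta_high > 0, eta_low > 0, angle >= 0)
  angle * sqrt(eta_high / eta_low)
}

#' Time to diffuse along the cell length
#'
#' One-dimensional mean first-traverse approximation t = L^2 / (2 D); used
#' for the intracellular transport of the tumble signal (phosphorylated
#' CheY) along elongated cells.
#'
#' @param length distance to traverse in um.
#' @param D molecular diffusivity in um^2/s (default 10, cytoplasmic CheY-P).
#' @return traverse time in seconds.
#' @examples
#' diffusion_traverse_time(10)   # 5 s along a 10 um cell
#' diffusion_traverse_time(1.7)  # ~0.15 s along a normal-size cell
#' @export
diffusion_traverse_time <- function(length, D = 10) {
  stopifnot(all(length > 0), D > 0)
  length^2 / (2 * D)
}

#' Straight run length before orientation is lost
#'
#' Distance v * tau covered at run speed v during one orientation time
#' constant tau.
#'
#' @param v run speed in um/s.
#' @param tau orientation time constant in s.
#' @return run length in um.
#' @examples
#' straight_run_length(16, 1.2)    # ~19 um for a normal-size cell
#' straight_run_length(11, 41.4)   # > 450 um for a 10 um cell
#' @export
straight_run_length <- function(v, tau) {
  stopifnot(all(v >= 0), all(tau >= 0))
  v * tau
}

#' Evaluate the forward models over a grid of cell lengths
#'
#' Convenience wrapper producing the model overlays as a data frame:
#' RFT speed, the two power-scaling speeds, the two tumble angular
#' velocities, the predicted tumble time and the implied mean |cos| of the
#' tumble angle (angular velocity times tumble time, capped at pi, through
#' the uniform-up-to-maximum model).
#'
#' @param lengths cell lengths in um.
#' @param width shared cell width in um.
#' @param ref a [reference_cell()].
#' @param flag a [flagellar_bundle()].
#' @param medium a [medium()].
#' @return data frame with one row per length.
#' @export
model_grid <- function(lengths, width = 0.7, ref = reference_cell(),
                       flag = flagellar_bundle(), medium = runtumble::medium()) {
  stopifnot(all(lengths >= width))
  rows <- lapply(lengths, function(L) {
    g <- ellipsoid_geometry(L, width)
    om_pd <- scaled_tumble_angular_velocity(g, ref, medium, "power_density")
    om_cp <- scaled_tumble_angular_velocity(g, ref, medium, "constant_power")
    tt <- predicted_tumble_time(L)
    data.frame(length_um = L,
               v_rft = rft_speed(g, flag, medium),
               v_power_density = scaled_speed(g, ref, medium, "power_density"),
               v_constant_power = scaled_speed(g, ref, medium, "constant_power"),
               omega_power_density = om_pd,
               omega_constant_power = om_cp,
               tumble_time = tt,
               abs_cos_power_density = expected_abs_cos_tumble(min(pi, max(1e-9, om_pd * tt))),
               abs_cos_constant_power = expected_abs_cos_tumble(min(pi, max(1e-9, om_cp * tt))))
  })
  do.call(rbind, rows)
}
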