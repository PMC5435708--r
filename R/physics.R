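# Prolate-spheroid Brownian hydrodynamics: Perrin friction factors,
# Einstein diffusivities, power relations and the passive time constant.
#
# Unit conventions: public interfaces take cell dimensions in micrometres and
# return diffusivities in um^2/s (translation) and rad^2/s (rotation).
# Friction coefficients are kept in SI (N s m^-1, N m s) because they are
# combined with SI viscosities and the Boltzmann constant internally.

#' Boltzmann constant (J/K)
#' @keywords internal
.kB <- 1.380649e-23

#' Cell geometry as a prolate ellipsoid of revolution
#'
#' The cell body is modelled as a rigid prolate spheroid whose full major
#' axis is the cell length and full minor axis the cell width. The aspect
#' ratio length/width is the morphological covariate of the whole analysis.
#'
#' @param length cell length in um (full major axis).
#' @param width cell width in um (full minor axis).
#' @return an object of class `ellipsoid_geometry` with fields `length`,
#'   `width` and `aspect_ratio`.
#' @examples
#' ellipsoid_geometry(1.7, 0.7)
#' @export
ellipsoid_geometry <- function(length, width) {
  stopifnot(is.numeric(length), is.numeric(width),
            base::length(length) == 1L, base::length(width) == 1L)
  if (!is.finite(length) || !is.finite(width) || width <= 0 || length < width)
    stop("invalid cell geometry: need length >= width > 0 (um)")
  structure(list(length = length, width = width,
                 aspect_ratio = length / width),
            class = "ellipsoid_geometry")
}

#' @export
print.ellipsoid_geometry <- function(x, ...) {
  cat(sprintf("prolate spheroid: length %.3g um, width %.3g um (aspect ratio %.3g)\n",
              x$length, x$width, x$aspect_ratio))
  invisible(x)
}

#' Suspending medium
#'
#' @param temperature absolute temperature in kelvin.
#' @param viscosity dynamic viscosity in Pa s; defaults to the pure-water
#'   value at `temperature` from [water_viscosity()].
#' @return an object of class `medium`.
#' @examples
#' medium(306.15)  # growth medium at 33 C, water viscosity
#' @export
medium <- function(temperature = 306.15, viscosity = water_viscosity(temperature)) {
  stopifnot(is.numeric(temperature), is.numeric(viscosity))
  if (temperature <= 0 || viscosity <= 0)
    stop("medium requires temperature > 0 K and viscosity > 0 Pa s")
  structure(list(temperature = temperature, viscosity = viscosity),
            class = "medium")
}

#' @export
print.medium <- function(x, ...) {
  cat(sprintf("medium: T = %.2f K, eta = %.4g Pa s\n", x$temperature, x$viscosity))
  invisible(x)
}

#' Dynamic viscosity of pure water
#'
#' Kestin-type correlation anchored at eta(20 C) = 1.002e-3 Pa s. Accuracy is
#' within a fraction of a percent over 0-40 C, the range relevant for
#' culture work; outside that range the smooth correlation is extrapolated.
#'
#' @param temperature absolute temperature in kelvin, 273 < T < 373.
#' @return dynamic viscosity in Pa s (kg m^-1 s^-1).
#' @examples
#' water_viscosity(306.15)  # ~7.49e-4 Pa s at 33 C
#' @export
water_viscosity <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 273) || any(temperature >= 373))
    stop("temperature out of range: need 273 < T < 373 K")
  tc <- temperature - 273.15
  lg <- ((20 - tc) / (tc + 96)) *
    (1.2364 - 1.37e-3 * (20 - tc) + 5.7e-6 * (20 - tc)^2)
  1.002e-3 * 10^lg
}

# Perrin bracket functions of the eccentricity u = sqrt(1 - (b/a)^2).
# br_a = (1+u^2)*atanh(u)/u - 1 enters the major-axis translation and the
# rotation about a minor axis; br_b = (3u^2-1)*atanh(u)/u + 1 the minor-axis
# translation. For u -> 0 both vanish as u^2; the series branches keep full
# relative precision through the sphere limit.
.perrin_brackets <- function(u) {
  if (u < 1e-3) {
    u2 <- u * u
    # br_a = u^2 * Ka, br_b = u^2 * Kb
    Ka <- 4 / 3 + (8 / 15) * u2 + (12 / 35) * u2^2
    Kb <- 8 / 3 + (4 / 5) * u2 + (16 / 35) * u2^2
    list(series = TRUE, Ka = Ka, Kb = Kb)
  } else {
    A <- atanh(u) / u
    list(series = FALSE,
         br_a = (1 + u^2) * A - 1,
         br_b = (3 * u^2 - 1) * A + 1)
  }
}

#' Perrin friction coefficients of a prolate spheroid
#'
#' Rigorous low-Reynolds-number friction factors for a rigid prolate
#' ellipsoid of revolution with semi-axes (length/2, width/2): translation
#' along the major and minor axes and rotation about a minor axis (the mode
#' that reorients the swimming direction). All reduce to the Stokes sphere
#' values 6*pi*eta*r and 8*pi*eta*r^3 as the aspect ratio approaches 1.
#'
#' @param geom an [ellipsoid_geometry()].
#' @param medium a [medium()].
#' @return an object of class `friction_set`: `f_t_major`, `f_t_minor`
#'   (N s m^-1) and `f_r_minor` (N m s).
#' @examples
#' friction_coefficients(ellipsoid_geometry(1.7, 0.7), medium(306.15, 0.76e-3))
#' @export
friction_coefficients <- function(geom, medium) {
  stopifnot(inherits(geom, "ellipsoid_geometry"), inherits(medium, "medium"))
  a <- geom$length / 2 * 1e-6
  b <- geom$width / 2 * 1e-6
  eta <- medium$viscosity
  u <- sqrt(max(0, 1 - (b / a)^2))
  br <- .perrin_brackets(u)
  if (br$series) {
    f_t_major <- 8 * pi * eta * a / br$Ka
    f_t_minor <- 16 * pi * eta * a / br$Kb
    f_r_minor <- (16 * pi * eta / 3) * a^3 * (2 - u^2) / br$Ka
  } else {
    f_t_major <- 16 * pi * eta * a * u^2 / (2 * br$br_a)
    f_t_minor <- 32 * pi * eta * a * u^2 / (2 * br$br_b)
    f_r_minor <- (32 * pi * eta / 3) * a^3 * u^2 * (2 - u^2) / (2 * br$br_a)
  }
  structure(list(f_t_major = f_t_major, f_t_minor = f_t_minor,
                 f_r_minor = f_r_minor),
            class = "friction_set")
}

#' @export
print.friction_set <- function(x, ...) {
  cat(sprintf("friction coefficients: f_t major %.4g, minor %.4g N s/m; f_r (minor axis) %.4g N m s\n",
              x$f_t_major, x$f_t_minor, x$f_r_minor))
  invisible(x)
}

#' Brownian diffusivities of a prolate spheroid
#'
#' Einstein relations D = kT/f applied to each Perrin friction coefficient.
#'
#' @inheritParams friction_coefficients
#' @return an object of class `diffusivity_set`: `D_t_major`, `D_t_minor`
#'   (um^2/s) and `D_r` (rad^2/s, rotation about a minor axis).
#' @examples
#' diffusivities(ellipsoid_geometry(1.7, 0.7), medium(306.15, 0.76e-3))
#' @export
diffusivities <- function(geom, medium) {
  f <- friction_coefficients(geom, medium)
  kT <- .kB * medium$temperature
  structure(list(D_t_major = kT / f$f_t_major * 1e12,
                 D_t_minor = kT / f$f_t_minor * 1e12,
                 D_r = kT / f$f_r_minor),
            class = "diffusivity_set")
}

#' @export
print.diffusivity_set <- function(x, ...) {
  cat(sprintf("Brownian diffusivities: D_t major %.4g, minor %.4g um^2/s; D_r %.4g rad^2/s\n",
              x$D_t_major, x$D_t_minor, x$D_r))
  invisible(x)
}

#' Theoretical time constant for loss of run orientation
#'
#' Time for the root-mean-square angular deviation of a passively rotating
#' ellipsoid to reach one radian: tau = 1/(2 D_r) = f_r/(2 k T).
#'
#' @inheritParams friction_coefficients
#' @return time constant in seconds.
#' @examples
#' theoretical_time_constant(ellipsoid_geometry(10, 0.7), medium(306.15, 0.76e-3))
#' @export
theoretical_time_constant <- function(geom, medium) {
  1 / (2 * diffusivities(geom, medium)$D_r)
}

#' Power dissipated in translation
#'
#' P_t = f_t v^2 for steady translation at low Reynolds number.
#'
#' @param f_t translational friction coefficient (N s m^-1).
#' @param v speed in um/s.
#' @return power in watts.
#' @export
power_translate <- function(f_t, v) {
  stopifnot(f_t > 0, v >= 0)
  f_t * (v * 1e-6)^2
}

#' Power dissipated in rotation
#'
#' P_r = f_r omega^2; the torque is M = f_r omega.
#'
#' @param f_r rotational friction coefficient (N m s).
#' @param omega angular velocity in rad/s.
#' @return power in watts.
#' @export
power_rotate <- function(f_r, omega) {
  stopifnot(f_r > 0, omega >= 0)
  f_r * omega^2
}

#' Low-Reynolds-number torque
#'
#' @inheritParams power_rotate
#' @return torque in N m.
#' @export
rotation_torque <- function(f_r, omega) {
  stopifnot(f_r > 0, omega >= 0)
  f_r * omega
}

#' Volume of the spheroidal cell
#'
#' V = (4/3) pi (length/2) (width/2)^2, consistent with the prolate
#' ellipsoid body model.
#'
#' @param geom an [ellipsoid_geometry()].
#' @return volume in um^3.
#' @export
spheroid_volume <- function(geom) {
  stopifnot(inherits(geom, "ellipsoid_geometry"))
  (4 / 3) * pi * (geom$length / 2) * (geom$width / 2)^2
}
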