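# Angle helpers shared across modules. All angles are radians.

#' Wrap angles to (-pi, pi]
#' @param x numeric vector of angles (radians).
#' @return angles wrapped into (-pi, pi].
#' @export
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Wrap angles to [0, 2*pi)
#' @param x numeric vector of angles (radians).
#' @return angles wrapped into [0, 2*pi).
#' @export
wrap_2pi <- function(x) x %% (2 * pi)

#' Unwrap a wrapped angle series
#'
#' Removes 2*pi jumps so that consecutive differences are the wrapped
#' (minimal) differences. Used before mean-square angular deviation fits.
#' @param x numeric vector of angles (radians), possibly wrapped.
#' @return continuous angle series with x[1] unchanged.
#' @export
unwrap_angle <- function(x) {
  if (length(x) < 2L) return(x)
  x[1L] + cumsum(c(0, wrap_pi(diff(x))))
}

# circular mean direction of a set of directional angles
circ_mean <- function(x) atan2(mean(sin(x)), mean(cos(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a
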