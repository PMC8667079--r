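# Angle helpers shared across modules. All public angles are in degrees.
# Azimuth convention (global): phi = 0 points to the top of the display /
# pattern / image and increases clockwise as displayed. In (row, col) image
# coordinates a unit step along azimuth phi is (drow, dcol) = (-cos phi, +sin phi).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into [0, 360)
#' @param x angle(s), degrees
#' @return wrapped angle(s), degrees
#' @keywords internal
wrap360 <- function(x) x %% 360

#' Wrap an axial angle (direction without sense) into [0, 180)
#' @param x angle(s), degrees
#' @return wrapped angle(s), degrees
#' @keywords internal
wrap180 <- function(x) x %% 180

# Circular separation of two azimuths, result in [0, 180]
circ_sep <- function(a, b) {
  d <- abs(wrap360(a) - wrap360(b))
  pmin(d, 360 - d)
}

# Separation of two axial angles (mod 180), result in [0, 90]
axial_sep <- function(a, b) {
  d <- abs(wrap180(a) - wrap180(b))
  pmin(d, 180 - d)
}

# Unit step in (row, col) coordinates for azimuth phi (degrees)
azimuth_step <- function(phi) {
  p <- deg2rad(phi)
  cbind(-cos(p), sin(p))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
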