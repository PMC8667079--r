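#' Display and measurement geometry
#'
#' Describes the physical layout of an SLI scatterometry rig: a square LED
#' display of `leds_per_side` x `leds_per_side` LEDs with a given pixel
#' pitch, placed a distance `source_sample_distance_mm` below the specimen
#' stage, with the camera `sample_camera_distance_mm` above it. During a
#' measurement a square kernel of `kernel_size` x `kernel_size` LEDs is
#' scanned over the display (`kernels_per_side` positions per side) and one
#' camera image is recorded per position.
#'
#' The defaults reproduce the rig used for published SLI scatterometry
#' measurements: a 256 x 256 RGB-LED panel with 1.8 mm pitch, 13 cm below
#' the sample, camera 40 cm above, 3.0 um/px object-space resolution.
#'
#' @param leds_per_side number of LEDs along one display side
#' @param pixel_pitch_mm distance between adjacent LEDs, mm
#' @param source_sample_distance_mm display-to-sample distance H, mm
#' @param sample_camera_distance_mm sample-to-camera distance L, mm
#' @param kernel_size LEDs per kernel side, n
#' @param kernels_per_side kernel positions per side, m
#' @param object_pixel_size_um object-space size of one camera pixel, um
#' @return an object of class `display_geometry`
#' @examples
#' geom <- display_geometry()
#' max_illumination_angle(geom) # about 60.6 degrees
#' @export
display_geometry <- function(leds_per_side = 256,
                             pixel_pitch_mm = 1.8,
                             source_sample_distance_mm = 130,
                             sample_camera_distance_mm = 400,
                             kernel_size = 8,
                             kernels_per_side = 32,
                             object_pixel_size_um = 3.0) {
  if (source_sample_distance_mm <= 0 || sample_camera_distance_mm <= 0 ||
      pixel_pitch_mm <= 0 || object_pixel_size_um <= 0)
    stopf("invalid geometry: all lengths must be > 0")
  if (leds_per_side < 1 || kernel_size < 1 || kernels_per_side < 1)
    stopf("invalid geometry: counts must be >= 1")
  if (kernel_size * kernels_per_side > leds_per_side)
    stopf("invalid geometry: kernel_size * kernels_per_side (%d) exceeds leds_per_side (%d)",
          kernel_size * kernels_per_side, leds_per_side)
  structure(list(
    leds_per_side = as.integer(leds_per_side),
    pixel_pitch_mm = pixel_pitch_mm,
    source_sample_distance_mm = source_sample_distance_mm,
    sample_camera_distance_mm = sample_camera_distance_mm,
    kernel_size = as.integer(kernel_size),
    kernels_per_side = as.integer(kernels_per_side),
    object_pixel_size_um = object_pixel_size_um
  ), class = "display_geometry")
}

#' @export
print.display_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "<display_geometry> %d x %d LEDs, pitch %.2f mm\n",
    "  H = %.1f mm (source-sample), L = %.1f mm (sample-camera)\n",
    "  kernel %d x %d LEDs, %d x %d positions, %.2f um/px\n",
    "  max illumination angle: %.1f deg\n"),
    x$leds_per_side, x$leds_per_side, x$pixel_pitch_mm,
    x$source_sample_distance_mm, x$sample_camera_distance_mm,
    x$kernel_size, x$kernel_size, x$kernels_per_side, x$kernels_per_side,
    x$object_pixel_size_um, max_illumination_angle(x)))
  invisible(x)
}

#' Maximum possible illumination angle of a display
#'
#' The largest polar angle under which the display can illuminate a point at
#' the display center-normal: `atan(half display width / H)`. For the default
#' geometry (256 LEDs, 1.8 mm pitch, H = 130 mm) this is about 60.6 degrees.
#'
#' @param geom a [display_geometry()]
#' @return polar angle, degrees
#' @export
max_illumination_angle <- function(geom) {
  stopifnot(inherits(geom, "display_geometry"))
  half_width <- geom$leds_per_side * geom$pixel_pitch_mm / 2
  rad2deg(atan2(half_width, geom$source_sample_distance_mm))
}

#' Illumination angle for a kernel position and image pixel
#'
#' Computes the polar angle theta and azimuth phi under which light from the
#' kernel centered at `(kernel_offset_x, kernel_offset_y)` reaches the sample
#' point directly above `pixel_offset_mm`. Kernel offsets are measured in
#' kernel widths (one unit = `kernel_size * pixel_pitch_mm`) from the display
#' center, x to the right and y toward the top of the display; the scan
#' positions of an m-per-side measurement are at offsets
#' `(-(m-1)/2, ..., +(m-1)/2)`, half-integers when `m` is even.
#'
#' The exact per-pixel angle is used (planar distance between kernel center
#' and the point beneath the pixel); for pixel offsets below the LED pitch
#' the difference from the display-center approximation is negligible.
#'
#' @param geom a [display_geometry()]
#' @param kernel_offset_x,kernel_offset_y kernel-center offset from display
#'   center, in kernel widths
#' @param pixel_offset_mm length-2 numeric, in-plane (x right, y up) offset of
#'   the image pixel from the display center axis, mm
#' @return list with `theta` (degrees, in \[0, 90)) and `phi` (degrees, in
#'   \[0, 360), 0 = top of display, clockwise)
#' @export
kernel_illumination_angle <- function(geom, kernel_offset_x, kernel_offset_y,
                                      pixel_offset_mm = c(0, 0)) {
  stopifnot(inherits(geom, "display_geometry"), length(pixel_offset_mm) == 2)
  kw <- geom$kernel_size * geom$pixel_pitch_mm
  # planar vector from the point beneath the pixel to the kernel center
  dx <- kernel_offset_x * kw - pixel_offset_mm[1]
  dy <- kernel_offset_y * kw - pixel_offset_mm[2]
  d <- sqrt(dx^2 + dy^2)
  theta <- rad2deg(atan2(d, geom$source_sample_distance_mm))
  phi <- if (d == 0) 0 else wrap360(rad2deg(atan2(dx, dy)))
  list(theta = theta, phi = phi)
}

#' Gnomonic ring radius for a polar angle
#'
#' Scattering patterns show the distribution of scattered light on a plane
#' (gnomonic projection), so a direction with polar angle theta lands at
#' radial distance `scale * tan(theta)` from the pattern center. Rings of
#' constant theta drawn every 10 degrees therefore grow farther apart with
#' increasing theta.
#'
#' @param theta polar angle(s), degrees, in \[0, 90)
#' @param scale pattern pixels per unit tangent
#' @return radial distance(s) in pattern pixels
#' @export
theta_ring_radius <- function(theta, scale = 1) {
  if (any(theta < 0 | theta >= 90))
    stopf("theta must be in [0, 90)")
  scale * tan(deg2rad(theta))
}

#' Diffusor calibration curve
#'
#' Computes the mean transmitted intensity of a central region of interest as
#' a function of illumination angle for a one-dimensional kernel scan along
#' the display center-line (the standard diffusor-plate calibration: an
#' 8 x 8 LED kernel moved over 32 positions x = -15.5..15.5, averaging the
#' inner 1000 x 1000 image pixels). Theta is signed by the side of the
#' display center the kernel sits on (negative for x < 0) so the curve has a
#' two-sided abscissa.
#'
#' @param series an [image_series()] holding a 1 x m scan (a single row of
#'   kernel positions)
#' @param geom a [display_geometry()]
#' @param roi side length of the central square region to average, pixels
#' @return data.frame with columns `theta_deg` and `mean_intensity`, one row
#'   per kernel position, ordered by position
#' @export
calibration_curve <- function(series, geom, roi = 1000) {
  stopifnot(inherits(series, "image_series"), inherits(geom, "display_geometry"))
  dm <- dim(series$images)
  H <- dm[1]; W <- dm[2]
  if (dm[3] != 1)
    stopf("calibration series must be a single row of kernel positions (got %d rows)", dm[3])
  m <- dm[4]
  if (roi > min(H, W))
    stopf("ROI (%d px) larger than the %d x %d image", roi, H, W)
  if (roi < 1) stopf("ROI must contain at least one pixel")
  r0 <- floor((H - roi) / 2) + 1L; c0 <- floor((W - roi) / 2) + 1L
  rows <- r0:(r0 + roi - 1L); cols <- c0:(c0 + roi - 1L)
  offs <- (seq_len(m) - 1) - (m - 1) / 2   # kernel widths from display center
  theta <- vapply(offs, function(x) {
    a <- kernel_illumination_angle(geom, x, 0)$theta
    sign(x) * a
  }, numeric(1))
  mi <- vapply(seq_len(m), function(j) mean(series$images[rows, cols, 1, j]), numeric(1))
  data.frame(theta_deg = theta, mean_intensity = mi)
}

#' Write a calibration curve to CSV
#' @param curve data.frame from [calibration_curve()]
#' @param path output file path
#' @return the path, invisibly
#' @export
write_calibration_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}

#' Number of images in an angular SLI measurement
#'
#' Angular SLI illuminates with a fixed polar angle and steps the azimuth in
#' increments of `delta_phi`, so a full turn needs `360 / delta_phi` images
#' (72 for 5-degree steps).
#'
#' @param delta_phi azimuthal step, degrees; must divide 360
#' @return image count (integer)
#' @export
angular_sli_image_count <- function(delta_phi) {
  if (360 %% delta_phi != 0) stopf("delta_phi must divide 360")
  as.integer(360 / delta_phi)
}

#' Minimum acquisition time of a scatterometry scan
#'
#' A scatterometry measurement records one image per kernel position, so
#' `m^2` images at `illumination_time_s` seconds each set a lower bound on
#' the total acquisition time (camera readout and movement excluded). A
#' 64 x 64 kernel scan at 3 s illumination takes at least 3.4 h.
#'
#' @param kernels_per_side kernel positions per side, m
#' @param illumination_time_s illumination time per image, seconds
#' @return minimum acquisition time, hours
#' @export
scatterometry_min_hours <- function(kernels_per_side, illumination_time_s) {
  kernels_per_side^2 * illumination_time_s / 3600
}
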