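#' Find the unscattered-light center of a scattering pattern
#'
#' The center is the region of maximum brightness: the centroid of all
#' pattern entries attaining the maximum intensity. The plain intensity
#' centroid is not used because scattering patterns of anisotropic tissue
#' are not radially symmetric. For an all-equal (degenerate) pattern the
#' geometric center is returned and flagged.
#'
#' @param pattern a [scattering_pattern()]
#' @return list with `center` (row, col; fractional allowed, 1-based) and
#'   `degenerate` (logical)
#' @export
find_center <- function(pattern) {
  v <- pattern$values
  if (!length(v)) stopf("empty pattern")
  mx <- max(v)
  if (mx == min(v)) {
    return(list(center = c((nrow(v) + 1) / 2, (ncol(v) + 1) / 2),
                degenerate = TRUE))
  }
  idx <- which(v == mx, arr.ind = TRUE)
  list(center = c(mean(idx[, 1]), mean(idx[, 2])), degenerate = FALSE)
}

#' Subpixel refinement of a pattern center
#'
#' Improves the pixel-quantized [find_center()] estimate by taking the
#' intensity-weighted centroid of the bright core: all pixels whose excess
#' over the pattern minimum reaches `core_fraction` of the full range,
#' weighted by that excess. The soft threshold keeps the estimate anchored
#' to the unscattered blob (reflex bands stay below it) and is unbiased for
#' a symmetric blob at any fractional position. A half-pixel center error
#' tilts the integrated profile (the steep unscattered blob leaks unevenly
#' into the first radial samples), so the analysis chain refines the center
#' before integrating.
#'
#' @param pattern a [scattering_pattern()]
#' @param core_fraction fraction of the min-max range defining the core
#' @return refined (row, col), fractional
#' @export
refine_center <- function(pattern, core_fraction = 0.75) {
  v <- pattern$values
  rng <- range(v)
  if (rng[1] == rng[2]) return(find_center(pattern)$center)
  w <- pmax(v - (rng[1] + core_fraction * (rng[2] - rng[1])), 0)
  c(sum(row(v) * w), sum(col(v) * w)) / sum(w)
}

#' Largest circle radius around a center inside a matrix
#'
#' Radius of the largest disc around `center` that lies fully inside the
#' pattern; the pattern is cropped to this circle before profile
#' integration so all azimuths are integrated over the same radial range.
#'
#' @param shape (rows, cols) of the pattern
#' @param center (row, col), 1-based, fractional allowed
#' @return radius in pattern pixels (distance to the nearest matrix edge)
#' @export
crop_radius <- function(shape, center) {
  if (center[1] < 1 || center[1] > shape[1] ||
      center[2] < 1 || center[2] > shape[2])
    stopf("center outside the pattern")
  min(center[1] - 1, shape[1] - center[1],
      center[2] - 1, shape[2] - center[2])
}

#' Bilinear interpolation in a scattering pattern
#'
#' @param pattern a [scattering_pattern()] or numeric matrix
#' @param point (row, col), 1-based fractional coordinates; must lie within
#'   the matrix (callers guarantee the crop circle is interior)
#' @return interpolated intensity
#' @export
bilinear_sample <- function(pattern, point) {
  v <- if (inherits(pattern, "scattering_pattern")) pattern$values else pattern
  bilinear_many(v, matrix(point, ncol = 2))
}

# Vectorized bilinear interpolation at an n x 2 matrix of (row, col) points.
bilinear_many <- function(v, pts) {
  r <- pts[, 1]; c <- pts[, 2]
  if (any(r < 1 | r > nrow(v) | c < 1 | c > ncol(v)))
    stopf("interpolation point outside the pattern")
  r0 <- pmin(floor(r), nrow(v) - 1L); c0 <- pmin(floor(c), ncol(v) - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nrow(v) + r0
  v00 <- v[i00];              v10 <- v[i00 + 1L]
  v01 <- v[i00 + nrow(v)];    v11 <- v[i00 + nrow(v) + 1L]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

#' Azimuthal SLI profile
#'
#' @description
#' Integrates the centered, circle-cropped scattering pattern radially for
#' each azimuth: starting at the top of the pattern and moving clockwise in
#' steps of `delta_phi`, intensities are summed from the center to the
#' outer circle in one-pixel steps, using bilinear interpolation at each
#' sampling position:
#'
#' `I(phi) = sum over r = 1..floor(R) of pattern(center + r * (-cos phi, +sin phi))`
#'
#' The center sample (r = 0) is excluded so the bright unscattered blob does
#' not add the same offset to every azimuth bin. Profiles of patterns with a
#' small crop radius carry that radius so downstream stages can drop
#' border pixels.
#'
#' @param pattern a [scattering_pattern()]; if `center`/`crop_radius` are
#'   unset they are computed via [find_center()] and [crop_radius()]
#' @param delta_phi azimuthal step, degrees; must divide 360
#' @param include_center include the r = 0 sample in every bin
#' @return an [sli_profile()]
#' @export
azimuthal_profile <- function(pattern, delta_phi = 1, include_center = FALSE) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  if (360 %% delta_phi != 0) stopf("delta_phi must divide 360")
  ctr <- pattern$center
  if (is.null(ctr)) ctr <- find_center(pattern)$center
  R <- pattern$crop_radius
  if (is.null(R)) R <- crop_radius(dim(pattern$values), ctr)
  nr <- floor(R)
  if (nr < 1) stopf("pattern too small: crop radius %.2f < 1 px", R)
  phis <- seq(0, 360 - delta_phi, by = delta_phi)
  steps <- azimuth_step(phis)                     # n_phi x 2
  radii <- seq_len(nr)
  # sampling points for all (phi, r) at once
  pr <- ctr[1] + outer(steps[, 1], radii)         # n_phi x nr
  pc <- ctr[2] + outer(steps[, 2], radii)
  vals <- bilinear_many(pattern$values, cbind(as.vector(pr), as.vector(pc)))
  dim(vals) <- c(length(phis), nr)
  I <- rowSums(vals)
  if (include_center)
    I <- I + bilinear_sample(pattern$values, ctr)
  sli_profile(I, delta_phi, radius_px = R, center = ctr)
}

#' Azimuthal SLI profile container
#'
#' A periodic curve I(phi) sampled at phi = 0, delta_phi, ...,
#' 360 - delta_phi (bin starts; phi = 0 is the top of the pattern,
#' increasing clockwise).
#'
#' @param values intensities at the sampled azimuths (>= 0)
#' @param delta_phi azimuthal step, degrees
#' @param radius_px crop radius of the source pattern (quality flag for
#'   border pixels)
#' @param center pattern center used, (row, col)
#' @return an object of class `sli_profile`
#' @export
sli_profile <- function(values, delta_phi, radius_px = NA_real_, center = NULL) {
  if (length(values) != 360 / delta_phi)
    stopf("profile length %d does not match delta_phi = %g", length(values), delta_phi)
  structure(list(values = as.numeric(values), delta_phi = delta_phi,
                 radius_px = radius_px, center = center),
            class = "sli_profile")
}

#' Azimuth grid of a profile
#' @param profile an [sli_profile()]
#' @return vector of bin-start azimuths, degrees
#' @export
profile_phis <- function(profile) {
  seq(0, 360 - profile$delta_phi, by = profile$delta_phi)
}

#' @export
print.sli_profile <- function(x, ...) {
  cat(sprintf("<sli_profile> %d bins (delta_phi = %g deg), radius %.1f px\n",
              length(x$values), x$delta_phi, x$radius_px))
  invisible(x)
}

#' Compute azimuthal profiles for every pixel of a pattern cube
#'
#' @param cube a `pattern_cube` from [assemble()]
#' @param delta_phi azimuthal step, degrees
#' @param min_radius_px profiles with a smaller crop radius are returned as
#'   `NULL` (border pixels under asymmetric illumination)
#' @param subpixel_center refine the center with [refine_center()] before
#'   integrating
#' @return H x W list-matrix of [sli_profile()]s (or `NULL`)
#' @export
cube_profiles <- function(cube, delta_phi = 1, min_radius_px = 4,
                          subpixel_center = TRUE) {
  dm <- dim(cube$patterns)
  out <- vector("list", dm[3] * dm[4])
  dim(out) <- c(dm[3], dm[4])
  for (y in seq_len(dm[3])) for (x in seq_len(dm[4])) {
    pat <- scattering_pattern(cube$patterns[, , y, x])
    fc <- find_center(pat)
    pat$center <- if (subpixel_center) refine_center(pat) else fc$center
    pat$crop_radius <- crop_radius(dim(pat$values), pat$center)
    if (fc$degenerate || pat$crop_radius < max(1, min_radius_px)) next
    out[[y, x]] <- azimuthal_profile(pat, delta_phi)
  }
  out
}

#' Write a table of profiles to CSV
#'
#' One row per image pixel: `y, x, center_row, center_col, radius_px` then
#' the profile values `I_0, I_<delta_phi>, ...`.
#'
#' @param profiles list-matrix from [cube_profiles()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_profiles_csv <- function(profiles, path) {
  dm <- dim(profiles)
  rows <- list()
  for (y in seq_len(dm[1])) for (x in seq_len(dm[2])) {
    p <- profiles[[y, x]]
    if (is.null(p)) next
    rows[[length(rows) + 1]] <- c(y = y, x = x,
                                  center_row = p$center[1],
                                  center_col = p$center[2],
                                  radius_px = p$radius_px, p$values)
  }
  if (!length(rows)) stopf("no valid profiles to write")
  df <- as.data.frame(do.call(rbind, rows))
  dphi <- 360 / (ncol(df) - 5)
  names(df)[-(1:5)] <- sprintf("I_%g", seq(0, 360 - dphi, by = dphi))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
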