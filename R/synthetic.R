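#' Fiber bundle description for the phantom simulator
#'
#' One bundle of parallel nerve fibers inside a phantom pixel. In-plane
#' bundles scatter light into an elongated reflex perpendicular to the fiber
#' direction; with increasing out-of-plane inclination the reflex is
#' displaced along the fiber direction and bends into an arc.
#'
#' @param direction in-plane fiber direction, degrees in \[0, 180)
#' @param inclination out-of-plane angle, degrees in \[0, 90\]
#' @param weight relative scattering strength (>= 0)
#' @param reflex_width angular std-dev of the reflex band cross-section,
#'   pattern pixels
#' @param reflex_halflength half-length of the reflex band, pattern pixels;
#'   `NULL` = 0.45 x pattern size at render time
#' @return an object of class `fiber_bundle`
#' @export
fiber_bundle <- function(direction, inclination = 0, weight = 1,
                         reflex_width = 2.5, reflex_halflength = NULL) {
  if (weight < 0) stopf("weight must be >= 0")
  if (inclination < 0 || inclination > 90) stopf("inclination must be in [0, 90]")
  structure(list(direction = wrap180(direction), inclination = inclination,
                 weight = weight, reflex_width = reflex_width,
                 reflex_halflength = reflex_halflength),
            class = "fiber_bundle")
}

#' Labeled fiber phantom
#'
#' A synthetic tissue section: every pixel of `label_map` carries a label,
#' and `constellations` maps each label to a list of [fiber_bundle()]s (an
#' empty list means isotropic, gray-matter-like scattering with no reflex).
#'
#' @param label_map integer matrix (H x W) of constellation labels
#' @param constellations named list: label -> list of [fiber_bundle()]
#' @param background_transmittance baseline transmitted intensity fraction
#' @return an object of class `sli_phantom`
#' @export
sli_phantom <- function(label_map, constellations, background_transmittance = 0.02) {
  label_map <- as.matrix(label_map)
  labs <- unique(as.vector(label_map))
  missing <- setdiff(as.character(labs), names(constellations))
  if (length(missing))
    stopf("label_map labels without constellation entry: %s",
          paste(missing, collapse = ", "))
  structure(list(label_map = label_map, constellations = constellations,
                 background_transmittance = background_transmittance),
            class = "sli_phantom")
}

#' Camera noise model
#'
#' Shot noise plus Gaussian read noise, shot averaging, and camera gain:
#' the expected photon count of a pixel with intensity I is
#' `I * shot_scale * illumination_time`; each shot draws
#' `Poisson(mu)/ (shot_scale * illumination_time) + N(0, read_sigma)`,
#' shots are averaged, and the gain factor is applied after averaging.
#' Fully deterministic for a given `seed`.
#'
#' @param shot_scale photons per intensity unit per second
#' @param read_sigma read-noise standard deviation, intensity units
#' @param gain multiplicative camera gain (applied after averaging)
#' @param illumination_time illumination time, seconds
#' @param n_shots number of shots averaged per kernel position (>= 1)
#' @param seed integer RNG seed
#' @return an object of class `noise_model`
#' @export
noise_model <- function(shot_scale = 1000, read_sigma = 0.01, gain = 1,
                        illumination_time = 1, n_shots = 1, seed = 1) {
  if (n_shots < 1) stopf("n_shots must be >= 1")
  structure(list(shot_scale = shot_scale, read_sigma = read_sigma,
                 gain = gain, illumination_time = illumination_time,
                 n_shots = as.integer(n_shots), seed = as.integer(seed)),
            class = "noise_model")
}

# Apply a noise model to an array of noiseless intensities. Restores the
# caller's RNG state so simulation noise never leaks into other code.
apply_noise <- function(values, noise) {
  if (is.null(noise)) return(values)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  scale <- noise$shot_scale * noise$illumination_time
  mu <- pmax(values, 0) * scale
  acc <- 0
  for (s in seq_len(noise$n_shots)) {
    shot <- stats::rpois(length(mu), mu) / scale +
      stats::rnorm(length(mu), 0, noise$read_sigma)
    acc <- acc + shot
  }
  out <- noise$gain * acc / noise$n_shots
  out <- pmax(out, 0)
  dim(out) <- dim(values)
  out
}

#' Render one synthetic scattering pattern
#'
#' Forward model of the scattering pattern of a single image pixel: a bright
#' Gaussian blob of unscattered light at `center`, plus one elongated reflex
#' band per fiber bundle running through the center perpendicular to the
#' bundle direction (Gaussian cross-section `reflex_width`, truncated at
#' `reflex_halflength`). For inclined bundles the band is displaced along
#' the fiber direction by `shift_scale * tan(inclination)` pattern pixels
#' and bent into an arc whose curvature grows with inclination. The whole
#' pattern is multiplied by the illumination falloff
#' `cos(theta)^vignetting_exponent`, with theta the illumination angle of
#' each pattern pixel, and camera noise is applied if a [noise_model()] is
#' given.
#'
#' @param constellation list of [fiber_bundle()]s (empty = isotropic)
#' @param geom a [display_geometry()]; sets the pattern size m and the
#'   angular scale of the falloff
#' @param center (row, col) of the unscattered-light center in pattern
#'   coordinates (1-based, fractional allowed); `NULL` = pattern middle
#' @param vignetting_exponent exponent q of the cos^q falloff
#' @param noise a [noise_model()] or `NULL`
#' @param center_amplitude peak intensity of the unscattered blob;
#'   `NULL` = `2 + 2 * sum(weights)` so the center always dominates
#' @param center_sigma std-dev of the center blob, pattern pixels
#' @param background baseline intensity added everywhere
#' @param shift_scale inclination displacement, pattern px per unit
#'   tan(inclination)
#' @param bend_scale curvature of the inclined-reflex arc (dimensionless)
#' @return a [scattering_pattern()] whose `center` is the rendered
#'   ground-truth center
#' @export
render_pattern <- function(constellation, geom, center = NULL,
                           vignetting_exponent = 4, noise = NULL,
                           center_amplitude = NULL, center_sigma = 1.5,
                           background = 0.02,
                           shift_scale = NULL, bend_scale = 0.5) {
  stopifnot(inherits(geom, "display_geometry"))
  m <- geom$kernels_per_side
  if (is.null(center)) center <- c((m + 1) / 2, (m + 1) / 2)
  if (center[1] < 1 || center[1] > m || center[2] < 1 || center[2] > m)
    stopf("center (%.1f, %.1f) outside the %d x %d pattern", center[1], center[2], m, m)
  if (is.null(shift_scale)) shift_scale <- m / 8
  wsum <- if (length(constellation)) sum(vapply(constellation, `[[`, 0, "weight")) else 0
  if (is.null(center_amplitude)) center_amplitude <- 2 + 2 * wsum

  rows <- matrix(seq_len(m), m, m) - center[1]
  cols <- matrix(seq_len(m), m, m, byrow = TRUE) - center[2]

  vals <- center_amplitude * exp(-(rows^2 + cols^2) / (2 * center_sigma^2)) + background

  for (b in constellation) {
    stopifnot(inherits(b, "fiber_bundle"))
    if (b$weight == 0) next
    L <- if (is.null(b$reflex_halflength)) 0.45 * m else b$reflex_halflength
    delta <- deg2rad(b$direction)
    uf <- c(-cos(delta), sin(delta))            # along the fiber (row, col)
    ur <- c(sin(delta), cos(delta))             # along the reflex band
    s <- shift_scale * tan(deg2rad(min(b$inclination, 85)))
    dr <- rows - s * uf[1]
    dc <- cols - s * uf[2]
    t <- dr * ur[1] + dc * ur[2]
    d <- dr * uf[1] + dc * uf[2]
    curv <- bend_scale * tan(deg2rad(min(b$inclination, 85))) / m
    deff <- d - curv * t^2
    vals <- vals + b$weight * exp(-deff^2 / (2 * b$reflex_width^2)) * (abs(t) <= L)
  }

  # illumination falloff: theta of each pattern pixel relative to the center
  kw <- geom$kernel_size * geom$pixel_pitch_mm
  dist_mm <- sqrt(rows^2 + cols^2) * kw
  theta <- atan2(dist_mm, geom$source_sample_distance_mm)
  vals <- vals * cos(theta)^vignetting_exponent

  vals <- apply_noise(vals, noise)
  scattering_pattern(vals, center = center)
}

#' Render a full synthetic image series
#'
#' Simulates the complete scatterometry measurement of a phantom: image
#' (i, j) of the series holds, at image pixel p, the value of pixel (i, j)
#' of the scattering pattern rendered for p. The unscattered center of each
#' pattern drifts linearly across the field of view (it follows the kernel
#' directly beneath the pixel): a pixel `x_mm` right of the field center has
#' its pattern center `drift_scale * x_mm / kernel_width` pattern pixels
#' right of the pattern middle.
#'
#' @param phantom an [sli_phantom()]
#' @param geom a [display_geometry()]
#' @param noise a [noise_model()] or `NULL`
#' @param drift_scale multiplier on the physical center drift (1 = physical;
#'   larger values exaggerate the drift for small test phantoms)
#' @param ... further arguments passed to [render_pattern()]
#' @return an [image_series()] of m x m images, each H x W
#' @export
render_stack <- function(phantom, geom, noise = NULL, drift_scale = 1, ...) {
  stopifnot(inherits(phantom, "sli_phantom"), inherits(geom, "display_geometry"))
  H <- nrow(phantom$label_map); W <- ncol(phantom$label_map)
  m <- geom$kernels_per_side
  kw_mm <- geom$kernel_size * geom$pixel_pitch_mm
  px_mm <- geom$object_pixel_size_um / 1000
  imgs <- array(0, dim = c(H, W, m, m))
  mid <- (m + 1) / 2
  centers <- array(NA_real_, dim = c(H, W, 2))
  for (y in seq_len(H)) {
    dy_mm <- (y - (H + 1) / 2) * px_mm    # downward in the image
    for (x in seq_len(W)) {
      dx_mm <- (x - (W + 1) / 2) * px_mm
      ctr <- c(mid + drift_scale * dy_mm / kw_mm,
               mid + drift_scale * dx_mm / kw_mm)
      ctr <- pmin(pmax(ctr, 1), m)
      centers[y, x, ] <- ctr
      lab <- as.character(phantom$label_map[y, x])
      pat <- render_pattern(phantom$constellations[[lab]], geom,
                            center = ctr, noise = NULL,
                            background = phantom$background_transmittance, ...)
      imgs[y, x, , ] <- pat$values
    }
  }
  imgs <- apply_noise(imgs, noise)
  image_series(imgs, kernel_size = geom$kernel_size,
               shots = if (is.null(noise)) 1L else noise$n_shots,
               illumination_time = if (is.null(noise)) 1 else noise$illumination_time,
               gain = if (is.null(noise)) 1 else noise$gain,
               centers = centers)
}

# Geometry used for profile fixtures: finer kernel scan (4 x 4 LEDs,
# 48 x 48 positions) so reflex peaks are well resolved at delta_phi = 1.
fixture_geometry <- function() {
  display_geometry(kernel_size = 4, kernels_per_side = 48)
}

#' Synthetic line-profile fixtures for a known fiber constellation
#'
#' Renders `n_profiles` scattering patterns from randomized fiber bundles of
#' the requested kind (directions jittered, weights and widths varied, shot
#' noise applied) and computes their azimuthal profiles. The expected
#' significant-peak counts are 2 for parallel in-plane fibers, 1 or 2 for
#' out-of-plane fibers (the displaced reflex can merge into a single broad
#' peak), 4 for two crossing bundles, and 6 for three crossing bundles.
#'
#' @param kind one of `"parallel_inplane"`, `"outofplane"`, `"crossing2"`,
#'   `"crossing3"`
#' @param n_profiles number of profiles to generate
#' @param seed integer seed; fixtures are reproducible
#' @param delta_phi azimuthal step of the profiles, degrees
#' @param geom a [display_geometry()]; default is a 4-LED kernel scanned
#'   over 48 x 48 positions
#' @param noise a [noise_model()] or `NULL` for noiseless fixtures; the seed
#'   inside is re-derived per profile from `seed`
#' @param keep_patterns keep the rendered patterns in the result (for
#'   full-chain evaluation)
#' @return list with `profiles` (list of [sli_profile()]), `expected_counts`
#'   (integer set), `truth` (list of ground-truth direction vectors, degrees)
#'   and optionally `patterns`
#' @export
region_fixture <- function(kind, n_profiles, seed = 1, delta_phi = 1,
                           geom = fixture_geometry(),
                           noise = noise_model(shot_scale = 1000,
                                               read_sigma = 0.01,
                                               n_shots = 1, seed = seed),
                           keep_patterns = FALSE) {
  kinds <- c("parallel_inplane", "outofplane", "crossing2", "crossing3")
  if (!kind %in% kinds)
    stopf("unknown fixture kind '%s' (expected one of %s)", kind,
          paste(kinds, collapse = ", "))
  if (n_profiles < 1) stopf("n_profiles must be >= 1")
  expected <- switch(kind,
    parallel_inplane = 2L, outofplane = c(1L, 2L),
    crossing2 = 4L, crossing3 = 6L)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  profiles <- vector("list", n_profiles)
  truth <- vector("list", n_profiles)
  patterns <- if (keep_patterns) vector("list", n_profiles) else NULL
  for (k in seq_len(n_profiles)) {
    base <- stats::runif(1, 0, 180)
    dirs <- switch(kind,
      parallel_inplane = base,
      outofplane = base,
      crossing2 = c(base, base + stats::runif(1, 70, 110)),
      crossing3 = c(base, base + 60 + stats::runif(1, -8, 8),
                    base + 120 + stats::runif(1, -8, 8)))
    dirs <- wrap180(dirs)
    incl <- if (kind == "outofplane") stats::runif(1, 50, 75) else 0
    bundles <- lapply(dirs, function(d)
      fiber_bundle(d, inclination = incl,
                   weight = stats::runif(1, 0.7, 1.3),
                   reflex_width = stats::runif(1, 2.0, 3.0)))
    ns <- if (is.null(noise)) NULL else
      noise_model(shot_scale = noise$shot_scale, read_sigma = noise$read_sigma,
                  gain = noise$gain, illumination_time = noise$illumination_time,
                  n_shots = noise$n_shots,
                  seed = (noise$seed + 7919L * k) %% .Machine$integer.max)
    pat <- render_pattern(bundles, geom, noise = ns)
    pat$center <- refine_center(pat)
    pat$crop_radius <- crop_radius(dim(pat$values), pat$center)
    profiles[[k]] <- azimuthal_profile(pat, delta_phi)
    truth[[k]] <- dirs
    if (keep_patterns) patterns[[k]] <- pat
  }
  out <- list(kind = kind, profiles = profiles, expected_counts = expected,
              truth = truth, seed = seed)
  if (keep_patterns) out$patterns <- patterns
  out
}
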