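#' Refine a peak position by the centroid of its tip
#'
#' The angular resolution of the sampled profile is improved by taking the
#' intensity-weighted circular centroid of the contiguous samples around the
#' peak whose (normalized) height reaches
#' `peak height - tip_fraction * prominence`.
#'
#' @param profile an [sli_profile()]
#' @param peak_index 1-based bin index of a significant local maximum
#' @param tip_fraction fraction of the prominence defining the peak tip
#' @return refined peak azimuth, degrees in \[0, 360)
#' @export
refine_peak <- function(profile, peak_index, tip_fraction = 0.06) {
  stopifnot(inherits(profile, "sli_profile"))
  x <- normalize_profile(profile$values)
  N <- length(x)
  at <- function(o) x[((peak_index - 1 + o) %% N) + 1]
  h <- x[peak_index]
  prom <- circular_prominence(x, peak_index)
  thr <- h - tip_fraction * prom
  # coarse contiguous support of the tip
  lo <- 0L; hi <- 0L
  while (lo > -(N - 1) && at(lo - 1L) >= thr) lo <- lo - 1L
  while (hi < N - 1 + lo && at(hi + 1L) >= thr) hi <- hi + 1L
  # resample the support densely (linear interpolation, 1/100 bin) so the
  # centroid sees the fractional threshold crossings at the tip borders
  offs <- seq(lo - 1, hi + 1, by = 0.01)
  base <- floor(offs); frac <- offs - base
  v <- (1 - frac) * vapply(base, at, numeric(1)) +
    frac * vapply(base + 1, at, numeric(1))
  ok <- v >= thr
  # keep the contiguous run containing the peak itself
  i0 <- which.min(abs(offs))
  l <- i0; r <- i0
  while (l > 1 && ok[l - 1]) l <- l - 1
  while (r < length(ok) && ok[r + 1]) r <- r + 1
  sel <- l:r
  centroid_off <- sum(offs[sel] * v[sel]) / sum(v[sel])
  wrap360(((peak_index - 1) + centroid_off) * profile$delta_phi)
}

#' Pair profile peaks at 180 +/- tolerance degrees
#'
#' In-plane fibers produce two opposite reflex peaks, so fiber directions
#' are read off peak pairs separated by about half a turn. This finds the
#' matching that (1) maximizes the number of pairs whose circular
#' separation lies within `180 +/- tolerance_deg` and (2) among all maximal
#' matchings minimizes the total deviation from 180 degrees. Each peak
#' belongs to at most one pair; leftovers are reported unpaired.
#'
#' @param peaks a `peak_set` from [find_significant_peaks()], or a numeric
#'   vector of peak azimuths (degrees)
#' @param tolerance_deg allowed deviation from 180 degrees
#' @return list with `pairs` (data.frame `phi1`, `phi2`, `separation`) and
#'   `unpaired` (numeric azimuths)
#' @export
pair_peaks <- function(peaks, tolerance_deg = 35) {
  phis <- if (is.data.frame(peaks)) peaks$phi_deg else as.numeric(peaks)
  phis <- sort(wrap360(phis))
  n <- length(phis)
  if (n < 2)
    return(list(pairs = data.frame(phi1 = numeric(0), phi2 = numeric(0),
                                   separation = numeric(0)),
                unpaired = phis))
  sep <- outer(phis, phis, circ_sep)
  ok <- sep >= (180 - tolerance_deg)       # circ_sep <= 180 always
  # recursive search over matchings: maximize count, then minimize deviation
  best <- list(count = -1L, dev = Inf, pairs = NULL)
  search <- function(remaining, pairs, dev) {
    cnt <- nrow(pairs)
    # bound: even pairing everything left cannot beat a strictly higher count
    if (cnt + length(remaining) %/% 2 < best$count) return()
    if (length(remaining) < 2) {
      if (cnt > best$count || (cnt == best$count && dev < best$dev))
        best <<- list(count = cnt, dev = dev, pairs = pairs)
      return()
    }
    i <- remaining[1]
    rest <- remaining[-1]
    for (j in rest) {
      if (ok[i, j])
        search(setdiff(rest, j), rbind(pairs, c(i, j)),
               dev + abs(sep[i, j] - 180))
    }
    search(rest, pairs, dev)               # leave peak i unpaired
  }
  search(seq_len(n), matrix(integer(0), 0, 2), 0)
  prs <- best$pairs
  if (is.null(prs) || nrow(prs) == 0)
    return(list(pairs = data.frame(phi1 = numeric(0), phi2 = numeric(0),
                                   separation = numeric(0)),
                unpaired = phis))
  paired_idx <- as.vector(prs)
  list(pairs = data.frame(phi1 = phis[prs[, 1]], phi2 = phis[prs[, 2]],
                          separation = sep[prs]),
       unpaired = phis[setdiff(seq_len(n), paired_idx)])
}

#' Fiber directions of one image pixel
#'
#' @param angles 0 to 4 in-plane direction angles, degrees in \[0, 180)
#' @param validity `"valid"`, `"none"` (no direction found) or
#'   `"too_many"` (more than four directions)
#' @return an object of class `fiber_directions`
#' @export
fiber_directions <- function(angles = numeric(0),
                             validity = if (length(angles)) "valid" else "none") {
  structure(list(angles = sort(wrap180(angles)), validity = validity),
            class = "fiber_directions")
}

#' In-plane fiber directions from peak pairs
#'
#' Each peak pair marks one scattering reflex; its axis is the axial
#' (mod-180) mean of the two peak azimuths, and since in-plane fibers
#' scatter perpendicular to their orientation, the fiber direction is the
#' axis rotated by `reflex_rotation` degrees (90 by default; settable to 0
#' for compatibility with toolchains that rotate internally). Near-duplicate
#' directions are merged; more than four distinct directions invalidate the
#' pixel.
#'
#' @param pairs result of [pair_peaks()] (or its `pairs` data.frame)
#' @param reflex_rotation rotation from reflex axis to fiber direction,
#'   degrees (90 or 0)
#' @param merge_tolerance_deg directions closer than this (axially) collapse
#'   into one
#' @return a [fiber_directions()]
#' @export
directions_from_pairs <- function(pairs, reflex_rotation = 90,
                                  merge_tolerance_deg = 0.5) {
  df <- if (is.data.frame(pairs)) pairs else pairs$pairs
  if (!nrow(df)) return(fiber_directions())
  axes <- mapply(function(a, b) {
    # axial circular mean via doubled angles
    s <- sin(2 * deg2rad(c(a, b))); cs <- cos(2 * deg2rad(c(a, b)))
    wrap180(rad2deg(atan2(mean(s), mean(cs))) / 2)
  }, df$phi1, df$phi2)
  dirs <- wrap180(axes + reflex_rotation)
  # merge duplicates (axial distance)
  merged <- numeric(0)
  for (d in sort(dirs)) {
    if (!length(merged) || all(axial_sep(merged, d) > merge_tolerance_deg))
      merged <- c(merged, d)
  }
  if (length(merged) > 4)
    return(fiber_directions(validity = "too_many"))
  fiber_directions(merged)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the per-pixel analysis chain.
#'
#' @param delta_phi azimuthal profile step, degrees
#' @param filter a [filter_params()], preset name, or `NULL` (no smoothing)
#' @param prominence_threshold peak significance threshold (normalized)
#' @param tip_fraction centroid-refinement tip fraction
#' @param pair_tolerance_deg pairing tolerance around 180 degrees
#' @param reflex_rotation 90 (reflexes perpendicular to fibers) or 0
#' @param min_radius_px minimum crop radius; smaller patterns are flagged
#'   invalid (border pixels)
#' @param min_contrast minimum relative modulation `(max - min) / max` of
#'   the raw profile; flatter profiles (isotropic scatterers) yield no
#'   direction instead of having their interpolation ripple blown up to
#'   full scale by the min-max normalization
#' @param subpixel_center refine the center estimate with [refine_center()]
#'   before integrating (removes the half-pixel quantization bias of the
#'   maximum-brightness centroid)
#' @return an object of class `analysis_config`
#' @export
analysis_config <- function(delta_phi = 1, filter = "sli-1deg",
                            prominence_threshold = 0.08, tip_fraction = 0.06,
                            pair_tolerance_deg = 35, reflex_rotation = 90,
                            min_radius_px = 4, min_contrast = 0.1,
                            subpixel_center = TRUE) {
  if (360 %% delta_phi != 0) stopf("delta_phi must divide 360")
  if (!reflex_rotation %in% c(0, 90)) stopf("reflex_rotation must be 0 or 90")
  if (is.character(filter)) filter <- filter_preset(filter)
  structure(list(delta_phi = delta_phi, filter = filter,
                 prominence_threshold = prominence_threshold,
                 tip_fraction = tip_fraction,
                 pair_tolerance_deg = pair_tolerance_deg,
                 reflex_rotation = reflex_rotation,
                 min_radius_px = min_radius_px,
                 min_contrast = min_contrast,
                 subpixel_center = subpixel_center),
            class = "analysis_config")
}

#' Full per-pixel analysis: pattern to fiber directions
#'
#' Composition of the whole chain for one scattering pattern: center
#' finding, circular cropping, azimuthal profile, low-pass smoothing, peak
#' detection, centroid refinement, 180-degree pairing and the
#' reflex-to-fiber rotation. Any stage failure (degenerate center, pattern
#' too small, no peaks) yields an invalid-pixel flag instead of an error.
#'
#' @param pattern a [scattering_pattern()]
#' @param config an [analysis_config()]
#' @return a [fiber_directions()]
#' @export
analyze_pixel <- function(pattern, config = analysis_config()) {
  tryCatch({
    fc <- find_center(pattern)
    if (fc$degenerate) return(fiber_directions())
    pattern$center <- if (config$subpixel_center) refine_center(pattern)
      else fc$center
    pattern$crop_radius <- crop_radius(dim(pattern$values), pattern$center)
    if (pattern$crop_radius < max(1, config$min_radius_px))
      return(fiber_directions())
    prof <- azimuthal_profile(pattern, config$delta_phi)
    if ((max(prof$values) - min(prof$values)) <
        config$min_contrast * max(prof$values))
      return(fiber_directions())
    if (!is.null(config$filter)) prof <- lowpass(prof, config$filter)
    pk <- find_significant_peaks(prof, config$prominence_threshold)
    if (!nrow(pk)) return(fiber_directions())
    pk$phi_deg <- vapply(pk$index, function(i)
      refine_peak(prof, i, config$tip_fraction), numeric(1))
    prs <- pair_peaks(pk, config$pair_tolerance_deg)
    directions_from_pairs(prs, config$reflex_rotation,
                          merge_tolerance_deg = config$delta_phi / 2)
  }, error = function(e) fiber_directions())
}

#' Fiber directions for every pixel of a pattern cube
#'
#' @param cube a `pattern_cube` from [assemble()]
#' @param config an [analysis_config()]
#' @return object of class `direction_map`: list with `angles`
#'   (H x W x 4 array, degrees, `NA` = undefined) and `validity`
#'   (H x W character matrix)
#' @export
analyze_cube <- function(cube, config = analysis_config()) {
  dm <- dim(cube$patterns)
  ang <- array(NA_real_, dim = c(dm[3], dm[4], 4))
  val <- matrix("none", dm[3], dm[4])
  for (y in seq_len(dm[3])) for (x in seq_len(dm[4])) {
    fd <- analyze_pixel(cube_pattern(cube, y, x), config)
    val[y, x] <- fd$validity
    if (length(fd$angles))
      ang[y, x, seq_along(fd$angles)] <- fd$angles
  }
  structure(list(angles = ang, validity = val), class = "direction_map")
}

#' Write a direction map as CSV
#'
#' One row per pixel: `y, x, n_directions, dir1..dir4` (empty for
#' undefined).
#' @param dirmap a `direction_map` from [analyze_cube()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_directions_csv <- function(dirmap, path) {
  dm <- dim(dirmap$angles)
  rows <- vector("list", dm[1] * dm[2])
  k <- 0L
  for (y in seq_len(dm[1])) for (x in seq_len(dm[2])) {
    a <- dirmap$angles[y, x, ]
    k <- k + 1L
    rows[[k]] <- c(y, x, sum(!is.na(a)), a)
  }
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("y", "x", "n_directions", paste0("dir", 1:4))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a direction map as a multi-channel float TIFF
#'
#' Four 32-bit float channels (dir1..dir4) holding direction angles scaled
#' to angle/180 in \[0, 1); undefined entries store the sentinel 1.0 (a
#' direction of exactly 180 degrees cannot occur).
#' @param dirmap a `direction_map`
#' @param path output TIFF path
#' @return `path`, invisibly
#' @export
write_directions_tiff <- function(dirmap, path) {
  a <- dirmap$angles / 180
  a[is.na(a)] <- 1
  tiff::writeTIFF(a, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a direction map written by [write_directions_tiff()]
#' @param path TIFF path
#' @return a `direction_map` (validity reconstructed as none/valid)
#' @export
read_directions_tiff <- function(path) {
  # 4-sample grayscale confuses some TIFF readers' photometric heuristics
  a <- suppressWarnings(tiff::readTIFF(path)) * 180
  a[a >= 180 - 1e-4] <- NA_real_
  val <- matrix(ifelse(apply(!is.na(a), c(1, 2), any), "valid", "none"),
                dim(a)[1], dim(a)[2])
  structure(list(angles = a, validity = val), class = "direction_map")
}
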