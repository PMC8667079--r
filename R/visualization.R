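#' Color of an in-plane fiber direction
#'
#' Maps a direction angle in \[0, 180) onto the hue wheel with factor 2
#' (hue = 2 * angle), full saturation and value, so that 0 and 180 degrees
#' coincide and the mapping is injective on \[0, 180).
#'
#' @param angle direction angle(s), degrees
#' @return n x 3 matrix of RGB values in \[0, 1\]
#' @export
orientation_color <- function(angle) {
  hue <- wrap360(2 * wrap180(angle)) / 360
  unname(t(grDevices::col2rgb(grDevices::hsv(hue, 1, 1)) / 255))
}

#' Recover the direction angle encoded by an RGB color
#' @param rgb length-3 vector or n x 3 matrix of RGB values in \[0, 1\]
#' @return angle(s), degrees in \[0, 180)
#' @export
color_to_orientation <- function(rgb) {
  m <- if (is.null(dim(rgb))) matrix(rgb, ncol = 3) else rgb
  h <- grDevices::rgb2hsv(t(m * 255), maxColorValue = 255)[1, ]
  wrap180(h * 360 / 2)
}

#' Hue-coded fiber orientation map
#'
#' Renders a direction map as an RGB image of 2 x 2 subpixels per image
#' pixel, so up to four crossing fiber directions stay visible per pixel:
#' one direction fills all four subpixels; two directions go to the main
#' and anti-diagonal (checker arrangement); three directions fill three
#' subpixels with the first direction repeated in the fourth; four fill one
#' each (row-major, ascending angle). Pixels without any determined
#' direction are black.
#'
#' @param dirmap a `direction_map` from [analyze_cube()], or an H x W x 4
#'   array of angles with `NA` for undefined
#' @return RGB array of dim (2H, 2W, 3), values in \[0, 1\]
#' @export
orientation_map <- function(dirmap) {
  ang <- if (inherits(dirmap, "direction_map")) dirmap$angles else dirmap
  H <- dim(ang)[1]; W <- dim(ang)[2]
  out <- array(0, dim = c(2 * H, 2 * W, 3))
  for (y in seq_len(H)) for (x in seq_len(W)) {
    a <- sort(ang[y, x, !is.na(ang[y, x, ])])
    n <- length(a)
    if (n == 0) next
    cols <- orientation_color(a)
    # subpixel order: (1,1), (1,2), (2,1), (2,2) within the 2x2 block
    fill <- switch(n,
      cols[c(1, 1, 1, 1), , drop = FALSE],
      cols[c(1, 2, 2, 1), , drop = FALSE],   # main diagonal vs anti-diagonal
      cols[c(1, 2, 3, 1), , drop = FALSE],   # first direction duplicated
      cols[c(1, 2, 3, 4), , drop = FALSE])
    ys <- 2 * y - 1; xs <- 2 * x - 1
    out[ys, xs, ] <- fill[1, ]
    out[ys, xs + 1, ] <- fill[2, ]
    out[ys + 1, xs, ] <- fill[3, ]
    out[ys + 1, xs + 1, ] <- fill[4, ]
  }
  out
}

#' Write an RGB array as PNG
#' @param img array (H, W, 3) in \[0, 1\]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_map_png <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

#' Fiber orientation distribution map (unit-vector overlay)
#'
#' Sacrifices single-pixel accuracy to show direction statistics per block:
#' for every B x B block of image pixels in which at least
#' `min_defined_fraction` of the pixels have a defined fiber direction, one
#' unit-length line segment per direction per pixel is emitted, all
#' centered on the block center, colored by [orientation_color()] and drawn
#' with a low alpha so the dominant orientation appears saturated while
#' single deviating vectors stay faintly visible. Blocks below the coverage
#' threshold emit nothing.
#'
#' @param dirmap a `direction_map` or H x W x 4 angle array
#' @param block block side length B, image pixels
#' @param alpha per-segment alpha value
#' @param min_defined_fraction minimum fraction of block pixels with at
#'   least one direction (threshold is inclusive)
#' @param segment_length segment length in display units (0.9 B keeps
#'   adjacent blocks from overlapping)
#' @return data.frame of segments: `x0, y0, x1, y1, angle, r, g, b, alpha`
#'   (x right, y down, in image-pixel units)
#' @export
distribution_map <- function(dirmap, block = 40, alpha = 0.1,
                             min_defined_fraction = 0.08,
                             segment_length = 0.9 * block) {
  ang <- if (inherits(dirmap, "direction_map")) dirmap$angles else dirmap
  if (block < 1) stopf("block must be >= 1")
  H <- dim(ang)[1]; W <- dim(ang)[2]
  segs <- list()
  for (by in seq_len(ceiling(H / block))) for (bx in seq_len(ceiling(W / block))) {
    ys <- ((by - 1) * block + 1):min(by * block, H)
    xs <- ((bx - 1) * block + 1):min(bx * block, W)
    blk <- ang[ys, xs, , drop = FALSE]
    defined <- apply(!is.na(blk), c(1, 2), any)
    if (mean(defined) < min_defined_fraction) next
    cy <- mean(range(ys)); cx <- mean(range(xs))
    a <- blk[!is.na(blk)]
    if (!length(a)) next
    cols <- orientation_color(a)
    # direction angle: 0 = up, clockwise -> (dx, dy) = (sin a, -cos a)
    dx <- sin(deg2rad(a)) * segment_length / 2
    dy <- -cos(deg2rad(a)) * segment_length / 2
    segs[[length(segs) + 1]] <- data.frame(
      x0 = cx - dx, y0 = cy - dy, x1 = cx + dx, y1 = cy + dy,
      angle = a, r = cols[, 1], g = cols[, 2], b = cols[, 3], alpha = alpha)
  }
  if (!length(segs))
    return(data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                      y1 = numeric(0), angle = numeric(0), r = numeric(0),
                      g = numeric(0), b = numeric(0), alpha = numeric(0)))
  do.call(rbind, segs)
}

#' Draw a distribution map to a PNG file
#' @param segments data.frame from [distribution_map()]
#' @param path output PNG path
#' @param size image extent `c(H, W)` in pixels; default from the segments
#' @param scale device pixels per image pixel
#' @return `path`, invisibly
#' @export
plot_distribution_png <- function(segments, path, size = NULL, scale = 2) {
  if (is.null(size))
    size <- c(max(c(segments$y0, segments$y1, 1)),
              max(c(segments$x0, segments$x1, 1)))
  grDevices::png(path, width = ceiling(size[2] * scale),
                 height = ceiling(size[1] * scale), bg = "black")
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot(NA, xlim = c(0, size[2]), ylim = c(size[1], 0),
                 xaxs = "i", yaxs = "i", axes = FALSE, xlab = "", ylab = "")
  if (nrow(segments))
    graphics::segments(segments$x0, segments$y0, segments$x1, segments$y1,
                       col = grDevices::rgb(segments$r, segments$g,
                                            segments$b, segments$alpha),
                       lwd = scale)
  invisible(path)
}

#' Write a distribution map as SVG line segments
#' @param segments data.frame from [distribution_map()]
#' @param path output SVG path
#' @param size image extent `c(H, W)`; default from the segments
#' @return `path`, invisibly
#' @export
write_distribution_svg <- function(segments, path, size = NULL) {
  if (is.null(size))
    size <- c(max(c(segments$y0, segments$y1, 1)),
              max(c(segments$x0, segments$x1, 1)))
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %g %g">', size[2], size[1]),
    '<rect width="100%" height="100%" fill="black"/>')
  if (nrow(segments)) {
    cols <- grDevices::rgb(segments$r, segments$g, segments$b)
    lines <- c(lines, sprintf(
      '<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" stroke="%s" stroke-opacity="%.3f" stroke-width="0.5"/>',
      segments$x0, segments$y0, segments$x1, segments$y1, cols, segments$alpha))
  }
  writeLines(c(lines, "</svg>"), path)
  invisible(path)
}

#' Color-wheel legend for orientation maps
#'
#' @param size legend side length, pixels
#' @return RGB array (size, size, 3); pixels outside the wheel are black
#' @export
color_wheel <- function(size = 128) {
  out <- array(0, dim = c(size, size, 3))
  ctr <- (size + 1) / 2
  for (y in seq_len(size)) for (x in seq_len(size)) {
    dy <- y - ctr; dx <- x - ctr
    r <- sqrt(dy^2 + dx^2)
    if (r > size / 2 || r < size / 6) next
    ang <- wrap180(rad2deg(atan2(dx, -dy)))
    out[y, x, ] <- orientation_color(ang)
  }
  out
}
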