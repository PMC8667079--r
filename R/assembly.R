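#' Scatterometry image series
#'
#' The raw data of an SLI scatterometry measurement: one H x W camera image
#' per kernel position of an m x m scan, stored as a 4-D array indexed
#' `[pixel_row, pixel_col, kernel_row, kernel_col]` together with the
#' acquisition metadata. Kernel position (1, 1) is the upper-left corner of
#' the display; the scan order on disk is configurable (row-major default).
#'
#' @param images 4-D numeric array, dim (H, W, m, m)
#' @param kernel_size LEDs per kernel side, n
#' @param shots number of shots averaged per position
#' @param illumination_time illumination time per shot, seconds
#' @param gain camera gain factor
#' @param centers optional H x W x 2 array of ground-truth pattern centers
#'   (carried by synthetic series)
#' @return an object of class `image_series`
#' @export
image_series <- function(images, kernel_size = 1, shots = 1,
                         illumination_time = 1, gain = 1, centers = NULL) {
  dm <- dim(images)
  if (length(dm) != 4) stopf("images must be a 4-D array (H, W, m, m)")
  if (dm[3] != dm[4] && dm[3] != 1)
    stopf("kernel grid must be m x m (or 1 x m for line scans), got %d x %d",
          dm[3], dm[4])
  structure(list(images = images,
                 meta = list(kernel_size = as.integer(kernel_size),
                             kernels_per_side = dm[4],
                             shots = as.integer(shots),
                             illumination_time = illumination_time,
                             gain = gain),
                 centers = centers),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  dm <- dim(x$images)
  cat(sprintf("<image_series> %d x %d kernel positions, %d x %d px images (n = %d, %d shot(s), gain %.3g)\n",
              dm[3], dm[4], dm[1], dm[2], x$meta$kernel_size, x$meta$shots, x$meta$gain))
  invisible(x)
}

#' Average repeated shots of one kernel position
#'
#' Up to four shots can be recorded for the same position of illuminated
#' LEDs; they are reduced to one frame by the pixel-wise arithmetic mean of
#' the raw frames.
#'
#' @param repeats list of numeric matrices (equal dimensions)
#' @return single matrix, the element-wise mean
#' @export
average_shots <- function(repeats) {
  if (!length(repeats)) stopf("need at least one shot")
  d1 <- dim(repeats[[1]])
  for (im in repeats)
    if (!identical(dim(im), d1)) stopf("shot dimensions differ")
  Reduce(`+`, repeats) / length(repeats)
}

#' Scattering pattern of one image pixel
#'
#' @param values m x m numeric matrix of intensities (>= 0)
#' @param center (row, col) of the unscattered-light center, 1-based,
#'   fractional allowed; `NULL` until determined
#' @param crop_radius radius of the largest centered circle inside the
#'   pattern, pixels; `NULL` until determined
#' @return an object of class `scattering_pattern`
#' @export
scattering_pattern <- function(values, center = NULL, crop_radius = NULL) {
  values <- as.matrix(values)
  if (!is.null(center)) {
    if (center[1] < 1 || center[1] > nrow(values) ||
        center[2] < 1 || center[2] > ncol(values))
      stopf("center outside the pattern")
  }
  structure(list(values = values, center = center, crop_radius = crop_radius),
            class = "scattering_pattern")
}

#' Pivot an image series into per-pixel scattering patterns
#'
#' The axis pivot at the heart of SLI scatterometry: for every image pixel
#' p, entry (i, j) of its m x m scattering pattern is the value of p in the
#' image recorded at kernel position (i, j). The first recorded image
#' (kernel in the display's upper-left corner) becomes the upper-left entry
#' of every pattern. Pixels are processed in bounded row blocks so the
#' working set beyond the output stays at `block_rows` image rows.
#'
#' @param series an [image_series()]
#' @param roi optional pixel window `list(rows = r1:r2, cols = c1:c2)`
#'   restricting which image pixels get a pattern (kernels are never
#'   restricted)
#' @param block_rows rows per processing block
#' @return an object of class `pattern_cube` with `patterns` array of dim
#'   (m, m, H, W) and the series metadata as provenance
#' @export
assemble <- function(series, roi = NULL, block_rows = 64L) {
  stopifnot(inherits(series, "image_series"))
  dm <- dim(series$images)
  rows <- if (is.null(roi)) seq_len(dm[1]) else roi$rows
  cols <- if (is.null(roi)) seq_len(dm[2]) else roi$cols
  if (min(rows) < 1 || max(rows) > dm[1] || min(cols) < 1 || max(cols) > dm[2])
    stopf("ROI outside image bounds")
  H <- length(rows); W <- length(cols)
  cube <- array(0, dim = c(dm[3], dm[4], H, W))
  for (start in seq(1L, H, by = block_rows)) {
    idx <- start:min(start + block_rows - 1L, H)
    # [H', W, m, m] -> [m, m, H', W]
    blk <- series$images[rows[idx], cols, , , drop = FALSE]
    cube[, , idx, ] <- aperm(blk, c(3, 4, 1, 2))
  }
  structure(list(patterns = cube, provenance = series$meta,
                 roi = list(rows = rows, cols = cols)),
            class = "pattern_cube")
}

#' Extract one scattering pattern from a cube
#' @param cube a `pattern_cube` from [assemble()] or [read_cube()]
#' @param y,x image-pixel row and column (relative to the cube's ROI)
#' @return a [scattering_pattern()]
#' @export
cube_pattern <- function(cube, y, x) {
  stopifnot(inherits(cube, "pattern_cube"))
  scattering_pattern(cube$patterns[, , y, x])
}

#' Re-serialize a pattern cube into an image series
#'
#' Inverse of [assemble()] (only meaningful for full-frame cubes): image
#' (i, j) at pixel p is pattern entry (i, j) of p.
#' @param cube a `pattern_cube`
#' @return an [image_series()]
#' @export
cube_to_series <- function(cube) {
  stopifnot(inherits(cube, "pattern_cube"))
  imgs <- aperm(cube$patterns, c(3, 4, 1, 2))
  image_series(imgs, kernel_size = cube$provenance$kernel_size,
               shots = cube$provenance$shots,
               illumination_time = cube$provenance$illumination_time,
               gain = cube$provenance$gain)
}

# ---- disk formats -----------------------------------------------------------

#' Write an image series as numbered TIFF files
#'
#' One 32-bit float TIFF per kernel position, named by the configurable
#' pattern (defaults to `i_{row}_{col}.tif`, row-major scan order from the
#' display's upper left), plus a `series.json` sidecar with the acquisition
#' metadata (and ground-truth centers for synthetic series).
#'
#' @param series an [image_series()]
#' @param dir output directory (created if needed)
#' @param name_fmt sprintf format with two integer slots (kernel row, col)
#' @param scale divide intensities by this before writing so stored samples
#'   lie in \[0, 1\]; `NULL` picks the series maximum. The scale is recorded
#'   in the sidecar and undone on read.
#' @return `dir`, invisibly
#' @export
write_series_tiff <- function(series, dir, name_fmt = "i_%03d_%03d.tif",
                              scale = NULL) {
  stopifnot(inherits(series, "image_series"))
  if (is.null(scale)) scale <- max(series$images, 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(series$images)
  for (i in seq_len(dm[3])) for (j in seq_len(dm[4])) {
    tiff::writeTIFF(series$images[, , i, j] / scale,
                    file.path(dir, sprintf(name_fmt, i, j)),
                    bits.per.sample = 32L)
  }
  meta <- series$meta
  meta$kernel_rows <- dm[3]
  meta$name_fmt <- name_fmt
  meta$scale <- scale
  if (!is.null(series$centers)) meta$centers <- as.vector(series$centers)
  jsonlite::write_json(meta, file.path(dir, "series.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read an image series from a directory of numbered TIFFs
#' @param dir directory written by [write_series_tiff()] (or any directory of
#'   per-kernel TIFFs plus a `series.json` naming the grid)
#' @return an [image_series()]
#' @export
read_series_tiff <- function(dir) {
  meta_path <- file.path(dir, "series.json")
  if (!file.exists(meta_path)) stopf("no series.json in %s", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  m <- meta$kernels_per_side
  name_fmt <- meta$name_fmt %||% "i_%03d_%03d.tif"
  rows_k <- if (!is.null(meta$kernel_rows)) meta$kernel_rows else m
  first <- file.path(dir, sprintf(name_fmt, 1L, 1L))
  if (!file.exists(first)) stopf("missing kernel image %s", first)
  im1 <- tiff::readTIFF(first)
  imgs <- array(0, dim = c(nrow(im1), ncol(im1), rows_k, m))
  missing <- character(0)
  for (i in seq_len(rows_k)) for (j in seq_len(m)) {
    f <- file.path(dir, sprintf(name_fmt, i, j))
    if (!file.exists(f)) { missing <- c(missing, sprintf("(%d, %d)", i, j)); next }
    imgs[, , i, j] <- tiff::readTIFF(f) * (meta$scale %||% 1)
  }
  if (length(missing))
    stopf("missing kernel positions: %s", paste(missing, collapse = " "))
  s <- image_series(imgs, kernel_size = meta$kernel_size, shots = meta$shots,
                    illumination_time = meta$illumination_time, gain = meta$gain)
  if (!is.null(meta$centers))
    s$centers <- array(meta$centers, dim = c(nrow(im1), ncol(im1), 2))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist a pattern cube as a chunked binary store
#'
#' Writes the cube as little-endian float32 chunks, one file per block of
#' image pixels, plus a JSON index with dimensions, chunk layout and
#' provenance. Chunks are sized so that reading one pattern touches exactly
#' one chunk; a full cube never has to be memory-resident to read from it.
#'
#' @param cube a `pattern_cube`
#' @param dir output directory
#' @param chunk_px image pixels per chunk side
#' @return `dir`, invisibly
#' @export
write_cube <- function(cube, dir, chunk_px = 32L) {
  stopifnot(inherits(cube, "pattern_cube"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(cube$patterns)  # (m, m, H, W)
  nby <- ceiling(dm[3] / chunk_px); nbx <- ceiling(dm[4] / chunk_px)
  for (by in seq_len(nby)) for (bx in seq_len(nbx)) {
    ys <- ((by - 1) * chunk_px + 1):min(by * chunk_px, dm[3])
    xs <- ((bx - 1) * chunk_px + 1):min(bx * chunk_px, dm[4])
    con <- file(file.path(dir, sprintf("chunk_%04d_%04d.bin", by, bx)), "wb")
    writeBin(as.vector(cube$patterns[, , ys, xs]), con, size = 4L,
             endian = "little")
    close(con)
  }
  idx <- list(dims = dm, chunk_px = chunk_px, provenance = cube$provenance)
  jsonlite::write_json(idx, file.path(dir, "cube.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a pattern cube (or a window of it) from a chunked store
#' @param dir directory written by [write_cube()]
#' @param roi optional `list(rows =, cols =)` window of image pixels
#' @return a `pattern_cube`
#' @export
read_cube <- function(dir, roi = NULL) {
  idx <- jsonlite::read_json(file.path(dir, "cube.json"), simplifyVector = TRUE)
  dm <- idx$dims; cp <- idx$chunk_px
  rows <- if (is.null(roi)) seq_len(dm[3]) else roi$rows
  cols <- if (is.null(roi)) seq_len(dm[4]) else roi$cols
  out <- array(0, dim = c(dm[1], dm[2], length(rows), length(cols)))
  for (by in unique(ceiling(rows / cp))) for (bx in unique(ceiling(cols / cp))) {
    ys <- ((by - 1) * cp + 1):min(by * cp, dm[3])
    xs <- ((bx - 1) * cp + 1):min(bx * cp, dm[4])
    f <- file.path(dir, sprintf("chunk_%04d_%04d.bin", by, bx))
    con <- file(f, "rb")
    blk <- readBin(con, numeric(), n = dm[1] * dm[2] * length(ys) * length(xs),
                   size = 4L, endian = "little")
    close(con)
    dim(blk) <- c(dm[1], dm[2], length(ys), length(xs))
    sel_y <- ys %in% rows; sel_x <- xs %in% cols
    out[, , match(ys[sel_y], rows), match(xs[sel_x], cols)] <-
      blk[, , sel_y, sel_x, drop = FALSE]
  }
  structure(list(patterns = out,
                 provenance = as.list(idx$provenance),
                 roi = list(rows = rows, cols = cols)),
            class = "pattern_cube")
}
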