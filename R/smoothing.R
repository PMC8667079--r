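#' Fourier low-pass filter parameters
#'
#' The profile smoother is a tanh-windowed low-pass filter in the Fourier
#' domain: a coefficient at normalized frequency `g = |f| / f_max` (with
#' `f_max` the Nyquist frequency of the sampled profile, length/2 cycles per
#' turn) is multiplied by
#'
#' `M(g) = 1 - [0.5 + 0.5 * tanh((g - cutoff) / width)]`
#'
#' `cutoff` sets the fraction of passing frequencies, `width` the sharpness
#' of the roll-off.
#'
#' @param cutoff cutoff frequency as a fraction of the maximum frequency,
#'   in (0, 1]
#' @param width window width (roll-off sharpness), in (0, 0.25]
#' @return an object of class `filter_params`
#' @export
filter_params <- function(cutoff, width) {
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must be in (0, 1]")
  if (width <= 0 || width > 0.25)
    stopf("width must be in (0, 0.25] (a step filter needs an explicit tiny width)")
  structure(list(cutoff = cutoff, width = width), class = "filter_params")
}

#' Named filter presets
#'
#' Grid-search optima of the detection rate over four reference fiber
#' constellations: `"sli-1deg"` (cutoff 0.04, width 0.125) for profiles with
#' 1-degree steps and `"sli-5deg"` (cutoff 0.40, width 0.225) for 5-degree
#' steps.
#'
#' @param name preset name
#' @return a [filter_params()]
#' @export
filter_preset <- function(name) {
  switch(name,
    "sli-1deg" = filter_params(0.04, 0.125),
    "sli-5deg" = filter_params(0.40, 0.225),
    stopf("unknown filter preset '%s'", name))
}

#' Closed-form filter gain
#' @param g normalized frequency(ies) in \[0, 1\]
#' @param params a [filter_params()]
#' @return multiplier M(g)
#' @export
lowpass_gain <- function(g, params) {
  1 - (0.5 + 0.5 * tanh((g - params$cutoff) / params$width))
}

#' Smooth an SLI profile with the tanh Fourier low-pass filter
#'
#' Takes the discrete Fourier transform of the periodic profile, multiplies
#' each coefficient by the gain [lowpass_gain()] at its normalized
#' frequency, and transforms back; the real part is returned with length
#' and azimuthal step unchanged. The filter is zero-phase (real, even
#' multiplier), so symmetric profiles stay symmetric. The multiplier is
#' applied to all coefficients including f = 0; the resulting uniform DC
#' attenuation is harmless because peak analysis uses min-max-normalized
#' profiles.
#'
#' @param profile an [sli_profile()] (length >= 4)
#' @param params a [filter_params()] or preset name
#' @return smoothed [sli_profile()]
#' @export
lowpass <- function(profile, params) {
  stopifnot(inherits(profile, "sli_profile"))
  if (is.character(params)) params <- filter_preset(params)
  stopifnot(inherits(params, "filter_params"))
  x <- profile$values
  N <- length(x)
  if (N < 4) stopf("profile too short to filter")
  k <- 0:(N - 1)
  f <- pmin(k, N - k)            # cycles per turn, symmetric spectrum
  g <- f / (N / 2)               # normalized by the Nyquist frequency
  out <- Re(stats::fft(stats::fft(x) * lowpass_gain(g, params),
                       inverse = TRUE)) / N
  sli_profile(out, profile$delta_phi, radius_px = profile$radius_px,
              center = profile$center)
}

# ---- peak detection ---------------------------------------------------------

# Min-max normalization to [0, 1]; a flat profile maps to all zeros.
normalize_profile <- function(x) {
  rng <- range(x)
  if (rng[2] == rng[1]) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Circular peak finder with plateau handling and prominences.
# Returns a data.frame (index, height, prominence) on the normalized signal;
# indices are 1-based bin indices (plateaus count once, at their midpoint).
find_profile_peaks <- function(values) {
  x <- normalize_profile(values)
  N <- length(x)
  empty <- data.frame(index = integer(0), height = numeric(0),
                      prominence = numeric(0))
  if (max(x) == min(x)) return(empty)
  # collapse consecutive equal values into runs (circularly)
  r <- rle(x)
  vals <- r$values; lens <- r$lengths
  starts <- cumsum(c(1, lens[-length(lens)]))
  if (length(vals) > 1 && vals[1] == vals[length(vals)]) {
    # merge the wrap-around run: treat last run as preceding the first
    lens[1] <- lens[1] + lens[length(lens)]
    starts[1] <- starts[length(starts)]          # run starts before wrap
    vals <- vals[-length(vals)]
    lens <- lens[-length(lens)]
    starts <- starts[-length(starts)]
  }
  nr <- length(vals)
  if (nr < 2) return(empty)
  peaks <- integer(0)
  for (i in seq_len(nr)) {
    prev <- vals[if (i == 1) nr else i - 1]
    nxt <- vals[if (i == nr) 1 else i + 1]
    if (vals[i] > prev && vals[i] > nxt) {
      mid <- starts[i] + (lens[i] - 1) %/% 2
      peaks <- c(peaks, ((mid - 1) %% N) + 1)
    }
  }
  if (!length(peaks)) return(empty)
  prom <- vapply(peaks, function(p) circular_prominence(x, p), numeric(1))
  out <- data.frame(index = peaks, height = x[peaks], prominence = prom)
  out[order(out$index), , drop = FALSE]
}

# Prominence of the peak at index p in circular signal x: walk each way until
# a strictly higher value appears, tracking the minimum; the prominence is
# the height above the higher of the two side minima.
circular_prominence <- function(x, p) {
  N <- length(x)
  h <- x[p]
  walk <- function(step) {
    lo <- h
    i <- p
    for (k in seq_len(N - 1)) {
      i <- ((i - 1 + step) %% N) + 1
      if (x[i] > h) return(lo)
      if (x[i] < lo) lo <- x[i]
    }
    lo  # no higher value: global (possibly tied) maximum
  }
  h - max(walk(-1L), walk(+1L))
}

#' Count significant peaks of a profile
#'
#' Normalizes the profile to \[0, 1\] by min-max, finds circular local
#' maxima (plateaus count once, at their midpoint) and counts those whose
#' prominence reaches the threshold. The number of significant peaks
#' reflects the fiber constellation: two for parallel in-plane fibers, four
#' for two crossing bundles, six for three.
#'
#' @param profile an [sli_profile()] or numeric vector
#' @param prominence_threshold minimum prominence, fraction of the
#'   normalized amplitude
#' @return peak count (integer)
#' @export
count_significant_peaks <- function(profile, prominence_threshold = 0.08) {
  x <- if (inherits(profile, "sli_profile")) profile$values else profile
  pk <- find_profile_peaks(x)
  sum(pk$prominence >= prominence_threshold)
}

#' Significant peaks with positions and prominences
#'
#' @param profile an [sli_profile()]
#' @param prominence_threshold minimum prominence on the normalized profile
#' @return object of class `peak_set`: data.frame with `phi_deg` (bin-start
#'   azimuth), `index`, `height`, `prominence`, sorted by azimuth
#' @export
find_significant_peaks <- function(profile, prominence_threshold = 0.08) {
  stopifnot(inherits(profile, "sli_profile"))
  pk <- find_profile_peaks(profile$values)
  pk <- pk[pk$prominence >= prominence_threshold, , drop = FALSE]
  pk$phi_deg <- (pk$index - 1) * profile$delta_phi
  structure(pk[, c("phi_deg", "index", "height", "prominence")],
            class = c("peak_set", "data.frame"))
}

#' Detection rate of a set of profiles
#'
#' Fraction of profiles whose (optionally smoothed) profile has (a) a
#' significant-peak count contained in `accepted_counts` and (b), for even
#' counts, all peaks pairable at 180 +/- 35 degrees.
#'
#' @param profiles list of [sli_profile()]s
#' @param accepted_counts integer set of acceptable peak counts
#' @param params a [filter_params()], preset name, or `NULL` for no smoothing
#' @param prominence_threshold peak significance threshold
#' @param pair_tolerance_deg pairing tolerance around 180 degrees
#' @return fraction in \[0, 1\]
#' @export
detection_rate <- function(profiles, accepted_counts, params = NULL,
                           prominence_threshold = 0.08,
                           pair_tolerance_deg = 35) {
  if (!length(accepted_counts)) stopf("accepted_counts must not be empty")
  if (!length(profiles)) stopf("need at least one profile")
  ok <- vapply(profiles, function(p) {
    if (!is.null(params)) p <- lowpass(p, params)
    pk <- find_significant_peaks(p, prominence_threshold)
    n <- nrow(pk)
    if (!n %in% accepted_counts) return(FALSE)
    if (n > 0 && n %% 2 == 0) {
      pr <- pair_peaks(pk, tolerance_deg = pair_tolerance_deg)
      if (nrow(pr$pairs) != n / 2) return(FALSE)
    }
    TRUE
  }, logical(1))
  mean(ok)
}

#' Grid search for the optimal filter parameters
#'
#' For every reference region (a set of profiles with a known expected peak
#' count), computes the detection rate over a grid of cutoff frequencies
#' and window widths. Each region's rate matrix is normalized by its
#' maximum so every fiber constellation is weighted equally (all-zero
#' regions are excluded with a warning), the matrices are summed, and the
#' grid cell with the highest sum wins; ties break to the lowest cutoff,
#' then the lowest width.
#'
#' @param fixtures named list: region -> `list(profiles =, accepted_counts =)`
#'   (the shape returned by [region_fixture()])
#' @param cutoffs cutoff grid (fractions); default 0.02 steps
#' @param widths width grid; default 0.025 steps over (0, 0.25]
#' @param prominence_threshold peak significance threshold
#' @return list with `params` (the optimum [filter_params()]) and `grid`, a
#'   data.frame (region, cutoff, width, rate) of all evaluated cells
#' @export
optimize_filter <- function(fixtures,
                            cutoffs = seq(0.02, 1, by = 0.02),
                            widths = seq(0.025, 0.25, by = 0.025),
                            prominence_threshold = 0.08) {
  if (!length(fixtures)) stopf("need at least one region")
  regions <- names(fixtures)
  if (is.null(regions)) regions <- paste0("region", seq_along(fixtures))
  rates <- list()
  summed <- matrix(0, length(cutoffs), length(widths))
  used <- 0L
  grid_rows <- list()
  for (rg in seq_along(fixtures)) {
    fx <- fixtures[[rg]]
    # accept both hand-built fixtures and region_fixture() results
    fx$accepted_counts <- fx$accepted_counts %||% fx$expected_counts
    mat <- matrix(0, length(cutoffs), length(widths))
    for (ci in seq_along(cutoffs)) for (wi in seq_along(widths)) {
      mat[ci, wi] <- detection_rate(fx$profiles, fx$accepted_counts,
                                    filter_params(cutoffs[ci], widths[wi]),
                                    prominence_threshold)
    }
    grid_rows[[rg]] <- data.frame(region = regions[rg],
                                  cutoff = rep(cutoffs, times = length(widths)),
                                  width = rep(widths, each = length(cutoffs)),
                                  rate = as.vector(mat))
    if (max(mat) == 0) {
      warning(sprintf("region '%s' has zero detection rate everywhere; excluded",
                      regions[rg]))
      next
    }
    summed <- summed + mat / max(mat)
    used <- used + 1L
    rates[[regions[rg]]] <- mat
  }
  if (used == 0L) stopf("all regions have zero detection rates")
  best <- which(summed == max(summed), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  list(params = filter_params(cutoffs[best[1]], widths[best[2]]),
       grid = do.call(rbind, grid_rows),
       summed = summed, cutoffs = cutoffs, widths = widths)
}

#' Write a detection-rate grid to CSV
#' @param opt result of [optimize_filter()]
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_detection_grid_csv <- function(opt, path) {
  utils::write.csv(opt$grid, path, row.names = FALSE)
  invisible(path)
}
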