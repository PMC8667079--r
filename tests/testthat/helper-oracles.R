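# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms/code paths than the package.

# Two-pass bilinear interpolation: interpolate along rows first, then along
# the column direction, one point at a time.
oracle_bilinear <- function(v, point) {
  r <- point[1]; c <- point[2]
  r0 <- min(floor(r), nrow(v) - 1); r1 <- r0 + 1
  c0 <- min(floor(c), ncol(v) - 1); c1 <- c0 + 1
  top <- v[r0, c0] + (c - c0) * (v[r0, c1] - v[r0, c0])
  bot <- v[r1, c0] + (c - c0) * (v[r1, c1] - v[r1, c0])
  top + (r - r0) * (bot - top)
}

# Ray-sum profile using the two-pass interpolator, loop-based.
oracle_profile <- function(v, center, delta_phi) {
  R <- floor(min(center[1] - 1, nrow(v) - center[1],
                 center[2] - 1, ncol(v) - center[2]))
  phis <- seq(0, 360 - delta_phi, by = delta_phi)
  sapply(phis, function(phi) {
    a <- phi * pi / 180
    s <- 0
    for (r in seq_len(R)) {
      s <- s + oracle_bilinear(v, c(center[1] - r * cos(a),
                                    center[2] + r * sin(a)))
    }
    s
  })
}

# Brute-force circular peak count with the same prominence definition:
# normalize by min-max, local maxima by strict neighbor comparison (no
# plateaus expected in the generic inputs this is used on), prominence by
# exhaustive walks.
oracle_peak_count <- function(x, threshold) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(0L)
  x <- (x - rng[1]) / (rng[2] - rng[1])
  N <- length(x)
  at <- function(i) x[((i - 1) %% N) + 1]
  count <- 0L
  for (i in seq_len(N)) {
    if (!(at(i) > at(i - 1) && at(i) > at(i + 1))) next
    h <- at(i)
    side_min <- function(step) {
      lo <- h
      for (k in 1:(N - 1)) {
        val <- at(i + step * k)
        if (val > h) return(lo)
        lo <- min(lo, val)
      }
      lo
    }
    prom <- h - max(side_min(1), side_min(-1))
    if (prom >= threshold) count <- count + 1L
  }
  count
}

# Exhaustive peak-pairing oracle: enumerate every subset of the candidate
# pair list, keep disjoint ones, pick max count then min total deviation.
oracle_pair_peaks <- function(phis, tolerance = 35) {
  phis <- sort(phis %% 360)
  n <- length(phis)
  csep <- function(a, b) { d <- abs(a - b) %% 360; min(d, 360 - d) }
  cand <- list()
  for (i in seq_len(max(n - 1, 0))) for (j in seq_len(n)[-seq_len(i)]) {
    if (csep(phis[i], phis[j]) >= 180 - tolerance)
      cand[[length(cand) + 1]] <- c(i, j)
  }
  best_count <- 0L; best_dev <- 0; best_pairs <- list()
  nc <- length(cand)
  if (nc > 0) {
    for (mask in 0:(2^nc - 1)) {
      sel <- which(bitwAnd(mask, 2^(seq_len(nc) - 1)) > 0)
      used <- unlist(cand[sel])
      if (anyDuplicated(used)) next
      dev <- sum(vapply(cand[sel], function(p)
        abs(csep(phis[p[1]], phis[p[2]]) - 180), numeric(1)))
      if (length(sel) > best_count ||
          (length(sel) == best_count && dev < best_dev)) {
        best_count <- length(sel); best_dev <- dev; best_pairs <- cand[sel]
      }
    }
  }
  list(count = best_count, dev = best_dev, pairs = best_pairs)
}

# Default geometries shared across tests.
test_geom <- function() display_geometry()
small_geom <- function(m = 16, n = 4)
  display_geometry(kernel_size = n, kernels_per_side = m)
profile_geom <- function() display_geometry(kernel_size = 4, kernels_per_side = 48)
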