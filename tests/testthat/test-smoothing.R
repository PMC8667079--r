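test_that("filter parameters are validated and presets resolve", {
  expect_error(filter_params(0.04, 0), "width")
  expect_error(filter_params(0, 0.1), "cutoff")
  expect_error(filter_params(1.2, 0.1), "cutoff")
  p1 <- filter_preset("sli-1deg")
  expect_equal(c(p1$cutoff, p1$width), c(0.04, 0.125))
  p5 <- filter_preset("sli-5deg")
  expect_equal(c(p5$cutoff, p5$width), c(0.40, 0.225))
  expect_error(filter_preset("sli-2deg"), "preset")
})

test_that("filter gains at DC and Nyquist match the tanh closed form", {
  for (params in list(filter_preset("sli-1deg"), filter_preset("sli-5deg"))) {
    M0 <- 1 - (0.5 + 0.5 * tanh((0 - params$cutoff) / params$width))
    M1 <- 1 - (0.5 + 0.5 * tanh((1 - params$cutoff) / params$width))
    # constant profile: output must be c * M(0)
    prof <- sli_profile(rep(3, 360), 1)
    out <- lowpass(prof, params)
    expect_lt(max(abs(out$values - 3 * M0)), 1e-9)
    # Nyquist sinusoid riding on a DC offset: amplitude scales by M(1)
    x <- 1 + 0.25 * cos(pi * (0:359))
    sm <- lowpass(sli_profile(x, 1), params)$values
    amp <- abs(mean(sm * cos(pi * (0:359))))        # Nyquist component
    expect_lt(abs(amp - 0.25 * M1), 1e-9)
  }
})

test_that("the filter is zero-phase, linear and shift-equivariant", {
  phis <- seq(0, 359)
  sym <- 1 + cos(2 * pi * (phis - 40) / 360)^2      # symmetric about 40 deg
  sm <- lowpass(sli_profile(sym, 1), "sli-1deg")$values
  idx <- function(a) ((a) %% 360) + 1
  for (d in c(3, 17, 60))
    expect_equal(sm[idx(40 + d)], sm[idx(40 - d)], tolerance = 1e-9)
  set.seed(5)
  a <- runif(72); b <- runif(72)
  lp <- function(x) lowpass(sli_profile(x, 5), "sli-5deg")$values
  expect_equal(lp(2 * a + 3 * b), 2 * lp(a) + 3 * lp(b), tolerance = 1e-9)
  shift <- function(x, k) c(x[(length(x) - k + 1):length(x)], x[1:(length(x) - k)])
  expect_equal(lp(shift(a, 7)), shift(lp(a), 7), tolerance = 1e-9)
})

test_that("peak counting matches constellations and the brute-force oracle", {
  phis <- seq(0, 359)
  expect_equal(count_significant_peaks(sin(pi * phis / 180)^2), 2L)
  expect_equal(count_significant_peaks(sin(2 * pi * phis / 180)^2), 4L)
  expect_equal(count_significant_peaks(rep(2, 360)), 0L)
  set.seed(6)
  for (k in 1:120) {
    n <- sample(c(24, 72, 360), 1)
    x <- as.vector(stats::filter(rnorm(n), rep(1 / 4, 4), circular = TRUE))
    thr <- runif(1, 0.02, 0.3)
    expect_identical(count_significant_peaks(x, thr),
                     as.integer(oracle_peak_count(x, thr)))
  }
})

test_that("plateaus count once, at their midpoint", {
  x <- rep(0, 72)
  x[10:13] <- 1           # 4-wide plateau
  x[40] <- 0.9
  pk <- find_significant_peaks(sli_profile(x, 5), 0.05)
  expect_equal(nrow(pk), 2)
  expect_true(11 %in% pk$index)    # midpoint of 10..13 (floor)
  # plateau wrapping across the origin
  y <- rep(0, 72); y[c(71, 72, 1, 2)] <- 1; y[36] <- 0.5
  pk2 <- find_significant_peaks(sli_profile(y, 5), 0.05)
  expect_equal(nrow(pk2), 2)
  expect_true(any(pk2$index %in% c(72, 1)))
})

test_that("detection rate honors expected counts and pairability", {
  fx <- region_fixture("crossing2", 30, seed = 12, noise = NULL)
  expect_equal(detection_rate(fx$profiles, 4L), 1.0)
  expect_equal(detection_rate(fx$profiles, 6L), 0.0)
  expect_error(detection_rate(fx$profiles, integer(0)), "empty")
  # rate equals an independent tally over the same smoothed profiles
  noisy <- region_fixture("crossing2", 60, seed = 13)
  params <- filter_preset("sli-1deg")
  rate <- detection_rate(noisy$profiles, 4L, params)
  tally <- 0
  for (p in noisy$profiles) {
    sm <- lowpass(p, params)
    pk <- find_significant_peaks(sm, 0.08)
    good <- nrow(pk) == 4
    if (good) {
      prs <- pair_peaks(pk, 35)
      good <- nrow(prs$pairs) == 2
    }
    tally <- tally + good
  }
  expect_equal(rate, tally / 60)
})

test_that("grid search normalizes per region and breaks ties low", {
  # noiseless parallel fixtures detect perfectly everywhere -> all cells tie
  fx <- list(parallel = list(
    profiles = region_fixture("parallel_inplane", 10, seed = 14,
                              noise = NULL)$profiles,
    accepted_counts = 2L))
  opt <- optimize_filter(fx, cutoffs = c(0.04, 0.1, 0.2),
                         widths = c(0.05, 0.125))
  expect_equal(opt$params$cutoff, 0.04)
  expect_equal(opt$params$width, 0.05)
  # argmax of the summed normalized matrices recomputed from the emitted grid
  noisy <- list(
    crossing2 = list(profiles = region_fixture("crossing2", 40, seed = 15)$profiles,
                     accepted_counts = 4L),
    parallel = list(profiles = region_fixture("parallel_inplane", 40,
                                              seed = 16)$profiles,
                    accepted_counts = 2L))
  cutoffs <- c(0.02, 0.06, 0.12, 0.3); widths <- c(0.05, 0.15, 0.25)
  opt2 <- optimize_filter(noisy, cutoffs = cutoffs, widths = widths)
  summed <- 0
  for (rg in unique(opt2$grid$region)) {
    sub <- opt2$grid[opt2$grid$region == rg, ]
    mat <- matrix(sub$rate[order(match(sub$width, widths),
                                 match(sub$cutoff, cutoffs))],
                  length(cutoffs), length(widths))
    if (max(mat) > 0) summed <- summed + mat / max(mat)
  }
  best <- which(summed == max(summed), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  expect_equal(opt2$params$cutoff, cutoffs[best[1]])
  expect_equal(opt2$params$width, widths[best[2]])
})

test_that("all-zero regions are excluded with a warning", {
  flat <- lapply(1:5, function(i) sli_profile(rep(1, 72), 5))
  fx <- list(dead = list(profiles = flat, accepted_counts = 4L),
             alive = list(profiles = region_fixture("parallel_inplane", 8,
                                                    seed = 17,
                                                    noise = NULL)$profiles,
                          accepted_counts = 2L))
  expect_warning(opt <- optimize_filter(fx, cutoffs = c(0.04, 0.1),
                                        widths = c(0.125)), "excluded")
  expect_error(suppressWarnings(
    optimize_filter(list(dead = list(profiles = flat, accepted_counts = 4L)),
                    cutoffs = c(0.04), widths = c(0.125))), "zero")
})
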