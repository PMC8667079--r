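test_that("centroid refinement recovers sub-bin peak positions", {
  phis <- seq(0, 359)
  # symmetric triangular peak whose apex falls between bins 100 and 101
  tri <- pmax(0, 1 - abs(((phis - 100.5 + 180) %% 360) - 180) / 8)
  prof <- sli_profile(tri, 1)
  pk <- find_significant_peaks(prof)
  expect_equal(refine_peak(prof, pk$index[1]), 100.5, tolerance = 0.02)
  # peak exactly on a bin with symmetric neighbors stays on that bin
  gauss <- exp(-(((phis - 240 + 180) %% 360) - 180)^2 / 50)
  prof2 <- sli_profile(gauss, 1)
  pk2 <- find_significant_peaks(prof2)
  expect_equal(refine_peak(prof2, pk2$index[1]), 240, tolerance = 1e-6)
})

test_that("refinement matches a dense-resampling centroid oracle", {
  phis <- seq(0, 359)
  # skewed peak: different widths left and right of the apex at 77 deg
  d <- ((phis - 77 + 180) %% 360) - 180
  skew <- exp(-d^2 / ifelse(d < 0, 2 * 6^2, 2 * 11^2))
  prof <- sli_profile(skew, 1)
  pk <- find_significant_peaks(prof)
  got <- refine_peak(prof, pk$index[1], tip_fraction = 0.06)
  # oracle: resample the same discrete profile at 0.01 deg by linear
  # interpolation and take the weighted centroid of the tip set
  dense_phi <- seq(0, 360 - 0.01, by = 0.01)
  lo <- floor(dense_phi); fr <- dense_phi - lo
  xv <- c(skew, skew[1])
  dense <- (1 - fr) * xv[lo + 1] + fr * xv[lo + 2]
  thr <- max(dense) - 0.06 * (max(dense) - min(dense))
  tip <- dense >= thr
  rel <- ((dense_phi - 77 + 180) %% 360) - 180   # unwrap around the apex
  oracle <- 77 + sum(rel[tip] * dense[tip]) / sum(dense[tip])
  expect_lt(abs(got - oracle), 0.1)
})

test_that("peak pairing matches the worked examples", {
  pr <- pair_peaks(c(30, 210))
  expect_equal(nrow(pr$pairs), 1)
  expect_equal(pr$pairs$separation, 180)
  pr2 <- pair_peaks(c(0, 90, 180, 270))
  expect_equal(nrow(pr2$pairs), 2)
  expect_equal(sort(pr2$pairs$phi1), c(0, 90))
  expect_equal(sort(pr2$pairs$phi2), c(180, 270))
  # three peaks: the matching with the smaller deviation from 180 wins
  pr3 <- pair_peaks(c(0, 150, 310))
  expect_equal(nrow(pr3$pairs), 1)
  expect_equal(c(pr3$pairs$phi1, pr3$pairs$phi2), c(150, 310))
  expect_equal(pr3$unpaired, 0)
  expect_equal(nrow(pair_peaks(numeric(0))$pairs), 0)
})

test_that("pairing agrees with exhaustive enumeration on random peak sets", {
  set.seed(20)
  for (k in 1:150) {
    n <- sample(0:6, 1)
    phis <- sort(sample(seq(0, 355, by = 5), n))
    got <- pair_peaks(phis)
    ref <- oracle_pair_peaks(phis)
    expect_equal(nrow(got$pairs), ref$count)
    dev <- sum(abs(got$pairs$separation - 180))
    expect_equal(dev, ref$dev, tolerance = 1e-9)
  }
})

test_that("fiber directions sit perpendicular to the reflex axis", {
  fd <- directions_from_pairs(data.frame(phi1 = 90, phi2 = 270))
  expect_equal(fd$angles, 0)
  fd2 <- directions_from_pairs(data.frame(phi1 = c(0, 90), phi2 = c(180, 270)))
  expect_equal(fd2$angles, c(0, 90))
  # axial wrap: peaks at 175 and 355 -> axis 175 -> direction 85
  fd3 <- directions_from_pairs(data.frame(phi1 = 175, phi2 = 355))
  expect_equal(fd3$angles, 85)
  # rotation switch off
  fd4 <- directions_from_pairs(data.frame(phi1 = 90, phi2 = 270),
                               reflex_rotation = 0)
  expect_equal(fd4$angles, 90)
  expect_equal(directions_from_pairs(data.frame(phi1 = numeric(0),
                                                phi2 = numeric(0)))$validity,
               "none")
})

test_that("full per-pixel analysis recovers known constellations", {
  geom <- profile_geom()
  iso <- render_pattern(list(), geom)
  expect_equal(analyze_pixel(iso)$validity, "none")
  one <- render_pattern(list(fiber_bundle(45)), geom)
  fd <- analyze_pixel(one)
  expect_equal(fd$validity, "valid")
  expect_equal(length(fd$angles), 1)
  expect_lt(axial_dist <- min(abs(fd$angles - 45), 180 - abs(fd$angles - 45)), 1)
  cross <- render_pattern(list(fiber_bundle(0), fiber_bundle(90)), geom)
  fd2 <- analyze_pixel(cross)
  expect_equal(length(fd2$angles), 2)
  three <- render_pattern(list(fiber_bundle(30), fiber_bundle(90),
                               fiber_bundle(150)), geom)
  fd3 <- analyze_pixel(three)
  expect_equal(length(fd3$angles), 3)
  for (tr in c(30, 90, 150))
    expect_lt(min(abs(fd3$angles - tr), 180 - abs(fd3$angles - tr)), 2)
})

test_that("analysis is rotation-equivariant and intensity-scale invariant", {
  geom <- profile_geom()
  base <- c(20, 110)
  fd0 <- analyze_pixel(render_pattern(lapply(base, fiber_bundle), geom))
  for (delta in c(10, 37.5, 81)) {
    fdr <- analyze_pixel(render_pattern(lapply(base + delta, fiber_bundle), geom))
    expect_equal(length(fdr$angles), 2)
    errs <- vapply(fd0$angles, function(a) {
      d <- abs((a + delta) %% 180 - fdr$angles)
      min(pmin(d, 180 - d))
    }, numeric(1))
    expect_lt(max(errs), 1.5)
  }
  pat <- render_pattern(lapply(base, fiber_bundle), geom)
  scaled <- scattering_pattern(pat$values * 37.2)
  expect_equal(analyze_pixel(scaled)$angles, analyze_pixel(pat)$angles)
})

test_that("most crossing-fiber pixels recover both directions within 3 deg", {
  fx <- region_fixture("crossing2", 80, seed = 21, keep_patterns = TRUE)
  hits <- 0
  for (k in seq_along(fx$patterns)) {
    fd <- analyze_pixel(fx$patterns[[k]])
    tr <- fx$truth[[k]]
    ok <- length(fd$angles) == 2 &&
      all(vapply(tr, function(t)
        min(pmin(abs(fd$angles - t), 180 - abs(fd$angles - t))) <= 3,
        logical(1)))
    hits <- hits + ok
  }
  expect_gte(hits / length(fx$patterns), 0.9)
})

test_that("degenerate pixels flag rather than abort, and maps serialize", {
  geom <- small_geom(m = 12)
  ph <- phantom_preset("crossing2", size = c(6, 6), border = 2)
  cube <- assemble(render_stack(ph, geom))
  dm <- analyze_cube(cube, analysis_config(delta_phi = 5, min_radius_px = 3))
  expect_equal(dim(dm$angles), c(6, 6, 4))
  expect_true(all(dm$validity %in% c("none", "valid", "too_many")))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_directions_csv(dm, csv)
  df <- read.csv(csv)
  expect_equal(nrow(df), 36)
  expect_true(all(df$n_directions >= 0 & df$n_directions <= 4))
  tif <- withr::local_tempfile(fileext = ".tif")
  write_directions_tiff(dm, tif)
  back <- read_directions_tiff(tif)
  expect_equal(back$angles, dm$angles, tolerance = 1e-4)
})
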