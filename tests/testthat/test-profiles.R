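test_that("center finding takes the centroid of maximal pixels", {
  v <- matrix(0, 40, 50); v[12, 30] <- 5
  expect_equal(find_center(scattering_pattern(v))$center, c(12, 30))
  v2 <- matrix(0, 20, 30); v2[10, 10] <- 7; v2[10, 20] <- 7
  expect_equal(find_center(scattering_pattern(v2))$center, c(10, 15))
  flat <- find_center(scattering_pattern(matrix(3, 9, 9)))
  expect_true(flat$degenerate)
  expect_equal(flat$center, c(5, 5))
})

test_that("center of a noiseless rendered pattern is within 0.5 px of truth", {
  geom <- profile_geom()
  for (ctr in list(c(24.5, 24.5), c(20, 30), c(28.2, 22.7))) {
    pat <- render_pattern(list(fiber_bundle(70)), geom, center = ctr)
    expect_lte(max(abs(find_center(pat)$center - ctr)), 0.5)
  }
})

test_that("subpixel refinement removes the half-pixel center quantization", {
  geom <- profile_geom()
  # even-sized noiseless pattern: true center on the half-integer grid
  pat <- render_pattern(list(fiber_bundle(70)), geom)
  expect_equal(refine_center(pat), c(24.5, 24.5), tolerance = 1e-6)
  # fractional centers, including an inclined (displaced-reflex) bundle
  for (ctr in list(c(20.3, 27.8), c(26.1, 22.4))) {
    pat <- render_pattern(list(fiber_bundle(10, inclination = 60)), geom,
                          center = ctr)
    expect_lt(max(abs(refine_center(pat) - ctr)), 0.15)
  }
  # under shot noise the refined center beats the quantized one
  set.seed(11)
  errs <- sapply(1:20, function(k) {
    pat <- render_pattern(list(fiber_bundle(runif(1, 0, 180))), geom,
                          center = c(24.5, 24.5),
                          noise = noise_model(seed = k))
    c(refined = max(abs(refine_center(pat) - 24.5)),
      quantized = max(abs(find_center(pat)$center - 24.5)))
  })
  expect_lt(mean(errs["refined", ]), mean(errs["quantized", ]))
  flat <- scattering_pattern(matrix(1, 9, 9))
  expect_equal(refine_center(flat), c(5, 5))
})

test_that("crop radius is the distance to the nearest edge", {
  expect_equal(crop_radius(c(81, 81), c(41, 41)), 40)
  expect_equal(crop_radius(c(81, 81), c(11, 41)), 10)
  expect_error(crop_radius(c(81, 81), c(0, 5)), "outside")
  # brute force: scan candidate radii against all boundary distances
  set.seed(2)
  for (k in 1:25) {
    shape <- c(sample(5:60, 1), sample(5:60, 1))
    ctr <- c(runif(1, 1, shape[1]), runif(1, 1, shape[2]))
    brute <- min(c(ctr[1] - 1, shape[1] - ctr[1], ctr[2] - 1, shape[2] - ctr[2]))
    expect_equal(crop_radius(shape, ctr), brute)
  }
})

test_that("bilinear sampling matches a two-pass interpolation oracle", {
  v <- matrix(c(0, 10, 0, 10), 2, 2)   # rows: (0,0) / (10,10)
  expect_equal(bilinear_sample(v, c(1.5, 1.5)), 5)
  set.seed(3)
  v2 <- matrix(runif(30 * 40), 30, 40)
  for (i in seq_len(30)) {
    p <- c(runif(1, 1, 29.99), runif(1, 1, 39.99))
    expect_equal(bilinear_sample(v2, p), oracle_bilinear(v2, p),
                 tolerance = 1e-9)
  }
  ip <- c(17, 23)
  expect_identical(bilinear_sample(v2, ip), v2[17, 23])
  expect_error(bilinear_sample(v2, c(0.5, 3)), "outside")
})

test_that("profiles of radially symmetric patterns are flat", {
  n <- 61; ctr <- c(31, 31)
  r <- sqrt((row(diag(n)) - ctr[1])^2 + (col(diag(n)) - ctr[2])^2)
  pat <- scattering_pattern(exp(-r^2 / 200) + 0.1, center = ctr,
                            crop_radius = 30)
  prof <- azimuthal_profile(pat, 1)
  expect_lt(max(prof$values) / min(prof$values), 1.01)
})

test_that("profile integration matches the independent ray oracle", {
  geom <- profile_geom()
  for (dirs in list(30, c(0, 90), c(20, 80, 140))) {
    pat <- render_pattern(lapply(dirs, fiber_bundle), geom)
    pat$center <- find_center(pat)$center
    pat$crop_radius <- crop_radius(dim(pat$values), pat$center)
    prof <- azimuthal_profile(pat, 5)
    ref <- oracle_profile(pat$values, pat$center, 5)
    expect_lt(max(abs(prof$values - ref)) / max(ref), 0.005)
  }
})

test_that("rotating a pattern by 90 degrees shifts the profile by 90/dphi bins", {
  geom <- display_geometry(kernel_size = 4, kernels_per_side = 49) # odd: exact center
  pat <- render_pattern(list(fiber_bundle(25), fiber_bundle(115)), geom)
  v <- pat$values
  rot <- t(v)[, rev(seq_len(nrow(v)))]     # 90 deg clockwise rotation
  p0 <- azimuthal_profile(scattering_pattern(v, center = c(25, 25),
                                             crop_radius = 24), 1)
  p90 <- azimuthal_profile(scattering_pattern(rot, center = c(25, 25),
                                              crop_radius = 24), 1)
  shifted <- c(p0$values[(length(p0$values) - 89):length(p0$values)],
               p0$values[1:(length(p0$values) - 90)])
  expect_lt(max(abs(p90$values - shifted)) / max(p0$values), 0.01)
})

test_that("profile integration is linear and scale-equivariant", {
  set.seed(4)
  A <- matrix(runif(41 * 41), 41, 41)
  B <- matrix(runif(41 * 41), 41, 41)
  ctr <- c(21, 21)
  prof <- function(v) azimuthal_profile(
    scattering_pattern(v, center = ctr, crop_radius = 20), 5)$values
  expect_equal(prof(A + B), prof(A) + prof(B), tolerance = 1e-9)
  expect_equal(prof(2 * A), 2 * prof(A), tolerance = 1e-12)
})

test_that("degenerate and undersized patterns are rejected or flagged", {
  tiny <- scattering_pattern(matrix(runif(4), 2, 2), center = c(1.5, 1.5),
                             crop_radius = 0.5)
  expect_error(azimuthal_profile(tiny, 1), "too small")
  expect_error(azimuthal_profile(scattering_pattern(matrix(1, 9, 9),
                                                    center = c(5, 5),
                                                    crop_radius = 4), 7),
               "divide")
})

test_that("cube profiles skip border pixels and write a CSV table", {
  geom <- small_geom(m = 12)
  ph <- phantom_preset("parallel_inplane", size = c(5, 5), border = 1)
  series <- render_stack(ph, geom)
  profs <- cube_profiles(assemble(series), delta_phi = 5, min_radius_px = 4)
  expect_equal(dim(profs), c(5, 5))
  expect_false(is.null(profs[[3, 3]]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_profiles_csv(profs, path)
  df <- read.csv(path)
  expect_equal(ncol(df), 5 + 72)
  got <- as.numeric(df[df$y == 3 & df$x == 3, -(1:5)])
  expect_equal(got, profs[[3, 3]]$values, tolerance = 1e-8)
})
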