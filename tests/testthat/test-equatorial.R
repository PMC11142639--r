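test_that("background estimator summarizes the oocyte interior", {
  # uniform interior -> that constant
  img <- goc_image(matrix(12, 128, 128), 0.2)
  oo <- oocyte_model(center = c(12.7, 12.7), radius = 8)
  expect_equal(estimate_background(img, oo), 12)

  # split-intensity interior: compare to a direct median over the
  # enumerated interior pixels
  m <- matrix(10, 128, 128)
  m[, 65:128] <- 20
  img2 <- goc_image(m, 0.2)
  yy <- (seq_len(128) - 1) * 0.2 - 12.7
  xx <- (seq_len(128) - 1) * 0.2 - 12.7
  inside <- sqrt(outer(yy^2, xx^2, "+")) <= 0.7 * 8
  expect_equal(estimate_background(img2, oo), median(m[inside]))
  expect_equal(estimate_background(img2, oo, statistic = "mean"),
               mean(m[inside]))

  # oocyte fully outside the image
  oo_out <- oocyte_model(center = c(500, 500), radius = 8)
  expect_error(estimate_background(img, oo_out), "empty")
})

test_that("profile extraction: constancy, sample count, bounds", {
  img <- goc_image(matrix(7, 256, 256), 0.1)
  oo <- oocyte_model(center = c(12.75, 12.75), radius = 6, zona_thickness = 4)
  prof <- extract_equatorial_profile(img, oo)
  expect_true(all(abs(prof$samples - 7) < 1e-12))
  rc <- 6 + 2
  expect_identical(length(prof$samples), as.integer(ceiling(2 * pi * rc / 0.1)))
  expect_true(all(diff(prof$arc_positions) > 0))
  # circle exiting the image bounds
  oo_big <- oocyte_model(center = c(12.75, 12.75), radius = 12)
  expect_error(extract_equatorial_profile(img, oo_big), "bounds")
})

test_that("generated radial structures appear as exactly n local maxima", {
  sp <- small_spec(n_tzp = 12)
  g <- generate_goc_2d(sp)
  prof <- extract_equatorial_profile(g$image, oocyte_of(g))
  bg <- estimate_background(g$image, oocyte_of(g))
  res <- count_tzp_peaks(prof, bg)
  expect_identical(res$raw_count, 12L)
})

test_that("peak rule matches manual application, including plateaus and wraparound", {
  # worked circular example: peaks at the 30 and the 25
  r <- count_tzp_peaks(c(10, 30, 12, 25, 11, 8), background = 15)
  expect_identical(r$peak_indices, c(2L, 4L))
  expect_identical(r$raw_count, 2L)

  # constant profile, background at or above it -> nothing
  expect_identical(count_tzp_peaks(rep(9, 20), 9)$raw_count, 0L)

  # plateau fails the strict inequality on one side
  expect_identical(count_tzp_peaks(c(10, 20, 20, 10, 5, 5), 15)$raw_count, 0L)

  # single impulse
  expect_identical(count_tzp_peaks(c(1, 1, 100, 1, 1, 1), 15)$raw_count, 1L)

  # circular wraparound: maximum at the first sample
  expect_identical(count_tzp_peaks(c(50, 1, 1, 1, 1, 1), 15)$peak_indices, 1L)

  expect_error(count_tzp_peaks(c(1, 2), 0), "3 samples")
})

test_that("peak count never exceeds half the sample count", {
  set.seed(1)
  for (i in 1:25) {
    n <- sample(8:60, 1)
    prof <- runif(n, 0, 100)
    r <- count_tzp_peaks(prof, background = runif(1, 0, 50))
    expect_lte(r$raw_count, floor(n / 2))
  }
})

test_that("counting is invariant to intensity scaling and 90-degree rotation", {
  sp <- small_spec(n_tzp = 10, noise_sd = 2)
  g <- generate_goc_2d(sp)
  oo <- oocyte_of(g)
  base <- count_tzp(g$image, oo)

  scaled <- goc_image(g$image$intensities * 3.7, g$image$pixel_size)
  expect_identical(count_tzp(scaled, oo)$raw_count, base$raw_count)

  # counterclockwise 90-degree raster rotation about the image centre maps
  # the sampling circle onto itself
  m <- g$image$intensities
  rot <- t(m)[nrow(m):1, ]
  expect_identical(count_tzp(goc_image(rot, g$image$pixel_size), oo)$raw_count,
                   base$raw_count)
})

test_that("diameter normalization is plain division with validation", {
  expect_equal(normalize_tzp_count(120, 60), 2)
  expect_equal(normalize_tzp_count(0, 70), 0)
  expect_equal(normalize_tzp_count(91, 70), 1.3)
  expect_error(normalize_tzp_count(10, 0), "diameter")
})

test_that("circle autofit recovers the synthetic oocyte cortex", {
  g <- generate_goc_2d(small_spec(n_tzp = 0))
  oo <- fit_oocyte_circle(g$image, zona_thickness = 4)
  expect_equal(oo$center, unname(g$truth$center_um), tolerance = 0.05)
  expect_equal(oo$radius, g$truth$oocyte_radius, tolerance = 0.02)
})
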