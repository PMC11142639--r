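test_that("sphericity formula: closed forms and scale invariance", {
  # sphere of any radius -> exactly 1
  r <- 3.7
  expect_equal(sphericity(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  # cube with analytic V = s^3, A = 6 s^2 -> (pi/6)^(1/3)
  s <- 4
  expect_equal(sphericity(s^3, 6 * s^2), (pi / 6)^(1 / 3), tolerance = 1e-12)
  # doubling volume at fixed shape leaves sphericity unchanged
  expect_equal(sphericity(2 * s^3, 6 * (2^(2 / 3)) * s^2),
               sphericity(s^3, 6 * s^2))
})

test_that("digitized sphere measures near-unit sphericity and true volume", {
  h <- 0.2; r <- 5
  m <- measure_cell(ball_mask(r, h), voxel_size = c(h, h, h))
  expect_equal(m$sphericity, 1, tolerance = 0.03)
  expect_equal(m$volume, 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_equal(m$surface_area, 4 * pi * r^2, tolerance = 0.03)
})

test_that("sphericity decreases with ellipsoid anisotropy at fixed volume", {
  h <- 0.25
  # equal-volume ellipsoids (abc = 27), increasingly prolate
  shapes <- list(c(3, 3, 3), c(4.5, 3, 2), c(6, 3, 1.5), c(9, 3, 1))
  psi <- vapply(shapes, function(s) {
    measure_cell(ellipsoid_mask(s[1], s[2], s[3], h),
                 voxel_size = c(h, h, h))$sphericity
  }, 0)
  expect_true(all(diff(psi) < 0))
})

test_that("anisotropic voxels are handled in physical units", {
  # same ball digitized on a 0.4 x 0.2 x 0.2 grid
  r <- 4
  x1 <- seq(-r - 0.8, r + 0.8, by = 0.4)
  x2 <- seq(-r - 0.4, r + 0.4, by = 0.2)
  q <- outer(outer(x1^2, x2^2, "+"), x2^2, "+")
  mask <- array(q <= r^2, c(length(x1), length(x2), length(x2)))
  m <- measure_cell(mask, voxel_size = c(0.4, 0.2, 0.2))
  expect_equal(m$volume, 4 / 3 * pi * r^3, tolerance = 0.02)
  expect_equal(m$sphericity, 1, tolerance = 0.04)
})

test_that("volume filter is exclusive and degenerate volumes are handled", {
  # synthetic cell whose voxel volume lands just under the cutoff
  g <- generate_goc_3d(small_spec3d(n_tzp = 0, seed = 9), n_cells = 1,
                       cell_radius_mean = 2.3)
  segs_all <- segment_cells(g$volume, 50, min_volume = 0)
  expect_length(segs_all, 1)
  v <- segs_all[[1]]$volume
  expect_lt(v, 100)
  expect_length(segment_cells(g$volume, 50, min_volume = 100), 0)
  # keeping the exact measured volume as the cutoff keeps the cell ("<" excl.)
  expect_length(segment_cells(g$volume, 50, min_volume = v), 1)

  # all-background volume -> 0 labels
  empty <- goc_volume(array(1, c(8, 8, 8)) * 0 + 1, c(0.3, 0.3, 0.3))
  expect_error(segment_cells(empty, 50), "range")
  empty2 <- goc_volume(array(c(1, 2), c(8, 8, 8)), c(0.3, 0.3, 0.3))
  expect_length(segment_cells(empty2, 1.5, min_volume = 100), 0)
})

test_that("filament length, width floor and degenerate cases", {
  expect_equal(filament_length(filament(rbind(c(0, 0, 0), c(3, 4, 0)))), 5)
  expect_equal(filament_length(filament(rbind(c(0, 0, 0)))), 0)
  expect_equal(filament_length(
    filament(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)))), 2)

  expect_equal(filament_mean_width(filament(rbind(c(0, 0, 0), c(1, 0, 0)),
                                            radii = 0.2)), 0.4)
  expect_equal(filament_mean_width(filament(rbind(c(0, 0, 0), c(1, 0, 0)),
                                            radii = 0.01)), 0.1)
  expect_equal(filament_mean_width(filament(rbind(c(0, 0, 0), c(1, 0, 0)),
                                            radii = c(0.1, 0.3))), 0.4)
})

test_that("filament-to-spots discretization honours its contracts", {
  straight <- filament(rbind(c(0, 0, 0), c(5, 0, 0)))
  ch <- filament_to_spots(straight, spacing = 1)
  expect_identical(nrow(ch$spots), 6L)
  expect_equal(ch$spots[1, ], c(0, 0, 0))
  expect_equal(ch$spots[6, ], c(5, 0, 0))

  shorty <- filament(rbind(c(0, 0, 0), c(0.05, 0, 0)))
  ch2 <- filament_to_spots(shorty, spacing = 0.2)
  expect_identical(nrow(ch2$spots), 2L)

  set.seed(3)
  for (i in 1:20) {
    f <- random_filament(sample(2:10, 1))
    L <- filament_length(f)
    ch <- filament_to_spots(f, spacing = 0.5)
    expect_gte(nrow(ch$spots) * 0.5, L - 0.5)
    # spot arc positions reproduce the polyline length
    expect_equal(ch$arc[length(ch$arc)], L)
  }
})

test_that("signed distance to the oocyte sphere surface", {
  oo <- oocyte_model(c(0, 0, 0), 30)
  expect_equal(distance_to_surface(c(40, 0, 0), oo), 10)
  expect_equal(distance_to_surface(c(0, 30, 0), oo), 0)
  expect_equal(distance_to_surface(c(0, 0, 0), oo), -30)
})

test_that("orientation statistic: radial, away, tangential cases", {
  oo <- oocyte_model(c(0, 0, 0), 30)
  toward <- filament(rbind(c(40, 0, 0), c(36, 0, 0)))
  m <- orientation_delta(toward, oo)
  expect_equal(m$delta, 4)
  expect_identical(m$orientation_class, "toward")

  away <- filament(rbind(c(38, 0, 0), c(42, 0, 0)))
  m2 <- orientation_delta(away, oo)
  expect_equal(m2$delta, -4)
  expect_identical(m2$orientation_class, "away")

  # chord with both endpoints at equal radius
  chord <- filament(rbind(c(35, 5, 0), c(35, -5, 0)))
  m3 <- orientation_delta(chord, oo)
  expect_equal(m3$delta, 0)
  expect_identical(m3$orientation_class, "neutral")
})

test_that("|delta| <= L and rigid-motion invariance over random filaments", {
  oo <- oocyte_model(c(0, 0, 0), 30)
  set.seed(8)
  # a right-handed rotation and translation applied to filament + oocyte
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tr <- c(5, -3, 11)
  for (i in 1:50) {
    f <- random_filament(sample(2:12, 1))
    m <- orientation_delta(f, oo)
    expect_lte(abs(m$delta), filament_length(f) + 1e-9)

    f2 <- filament(t(R %*% t(f$points)) +
                     matrix(tr, nrow(f$points), 3, byrow = TRUE), f$radii)
    oo2 <- oocyte_model(as.numeric(R %*% oo$center) + tr, oo$radius)
    m2 <- orientation_delta(f2, oo2)
    expect_equal(m2$delta, m$delta, tolerance = 1e-10)
    expect_equal(filament_length(f2), filament_length(f), tolerance = 1e-10)
  }
})

test_that("spot distances along a straight radial filament are affine in index", {
  oo <- oocyte_model(c(0, 0, 0), 30)
  f <- filament(rbind(c(42, 0, 0), c(36, 0, 0)))
  ch <- filament_to_spots(f, spacing = 1)
  d <- distance_to_surface(ch$spots, oo)
  expect_equal(diff(d), rep(-1, length(d) - 1), tolerance = 1e-10)
})

test_that("per-cell aggregation: proportions, empty cells, conservation", {
  oo <- oocyte_model(c(0, 0, 0), 30)
  mk <- function(cell, from, to) {
    f <- filament(rbind(from, to), parent_cell = cell)
    orientation_delta(f, oo)
  }
  metrics <- rbind(mk("A", c(40, 0, 0), c(36, 0, 0)),
                   mk("A", c(41, 0, 0), c(37, 0, 0)),
                   mk("A", c(38, 0, 0), c(42, 0, 0)))
  agg <- aggregate_per_cell(metrics, cells = c("A", "B"))
  expect_identical(agg$n_tzp, c(3L, 0L))
  expect_equal(agg$away_proportion[1], 1 / 3)
  expect_true(is.na(agg$away_proportion[2]))
  expect_true(is.na(agg$mean_length[2]))

  # orphan filaments are rejected
  orphan <- metrics
  orphan$parent_cell[1] <- NA
  expect_error(aggregate_per_cell(orphan), "orphan")

  # conservation: per-cell counts sum to the number of filaments
  set.seed(12)
  fls <- lapply(1:30, function(i)
    random_filament(4, parent = sample(letters[1:5], 1)))
  mm <- measure_filaments(fls, oo)
  agg2 <- aggregate_per_cell(mm)
  expect_identical(sum(agg2$n_tzp), 30L)
})

test_that("sphere fit recovers centre and radius from surface points", {
  set.seed(5)
  th <- runif(200, 0, 2 * pi); ph <- acos(runif(200, -1, 1))
  pts <- cbind(30 * sin(ph) * cos(th), 30 * sin(ph) * sin(th),
               30 * cos(ph))
  pts <- sweep(pts, 2, c(1, -2, 3), "+")
  oo <- fit_oocyte_sphere(pts)
  expect_equal(oo$center, c(1, -2, 3), tolerance = 1e-8)
  expect_equal(oo$radius, 30, tolerance = 1e-8)
})
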