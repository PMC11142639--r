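test_that("generator is deterministic and intensity scaling leaves geometry truth unchanged", {
  sp <- small_spec(noise_sd = 4)
  a <- generate_goc_2d(sp)
  b <- generate_goc_2d(sp)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$truth$angles, b$truth$angles)

  # scale every intensity parameter by c > 0: geometric truth identical
  spc <- small_spec(noise_sd = 4 * 3, tzp_intensity = 300,
                    cytoplasm_intensity = 120, background_intensity = 15,
                    zona_intensity = 24, cortex_intensity = 270)
  cc <- generate_goc_2d(spc)
  expect_equal(cc$truth$angles, a$truth$angles)
  expect_equal(cc$truth$n_tzp, a$truth$n_tzp)
})

test_that("noiseless structure-free image gives a constant mid-zona profile", {
  sp <- small_spec(n_tzp = 0)
  g <- generate_goc_2d(sp)
  prof <- extract_equatorial_profile(g$image, oocyte_of(g))
  expect_true(diff(range(prof$samples)) < 1e-9)
})

test_that("noiseless generated TZPs are recovered exactly by peak counting", {
  for (n in c(8L, 25L, 40L)) {
    sp <- goc_spec(n_tzp = n, tzp_width_mean = 0.1, noise_sd = 0, seed = n)
    g <- generate_goc_2d(sp)
    res <- count_tzp(g$image, oocyte_of(g))
    expect_identical(res$raw_count, n)
  }
})

test_that("impossible geometries are rejected with explicit errors", {
  expect_error(generate_goc_2d(goc_spec(oocyte_radius = 30,
                                        image_shape = c(256L, 256L))),
               "image too small")
  # unresolvable angular separation at the mid-zona radius
  expect_error(generate_goc_2d(goc_spec(oocyte_radius = 5,
                                        zona_thickness = 2, n_tzp = 200,
                                        image_shape = c(512L, 512L))),
               "unresolvable")
  expect_error(goc_spec(zona_thickness = -1), "zona_thickness")
  expect_error(goc_spec(away_fraction = 1.2), "away_fraction")
})

test_that("3D generator: radial filament truth, away class, overlap rejection", {
  # one straight radial filament of length 5 um -> delta = 5 um
  sp <- small_spec3d(n_tzp = 1, tzp_length_mean = 5, tzp_length_sd = 0,
                     zona_thickness = 7)
  g <- generate_goc_3d(sp, n_cells = 1)
  m <- orientation_delta(g$truth$filaments[[1]], g$oocyte)
  expect_equal(m$length, 5, tolerance = 1e-9)
  expect_equal(m$delta, 5, tolerance = 1e-9)
  expect_identical(m$orientation_class, "toward")

  # away_fraction = 1 forces every orientation class to "away"
  spa <- small_spec3d(n_tzp = 5, away_fraction = 1)
  ga <- generate_goc_3d(spa, n_cells = 2)
  expect_true(all(ga$truth$orientation_classes == "away"))
  ma <- measure_filaments(ga$truth$filaments, ga$oocyte)
  expect_true(all(ma$orientation_class == "away"))

  # overlapping requested centres are rejected
  expect_error(
    generate_goc_3d(small_spec3d(n_tzp = 0), n_cells = 2,
                    cell_centers = rbind(c(18, 0, 0), c(19, 0, 0))),
    "overlap")
})

test_that("3D segmentation recovers well-separated cells and their volumes", {
  g <- generate_goc_3d(small_spec3d(n_tzp = 0, seed = 3), n_cells = 2)
  segs <- segment_cells(g$volume, 50)
  expect_length(segs, 2)
  v <- sort(vapply(segs, `[[`, 0, "volume"))
  expect_equal(v, sort(g$truth$cell_volumes), tolerance = 0.05)
})

test_that("group simulation: null case, minimal n, effect recovery", {
  base <- goc_spec(n_tzp = 16)
  null_sim <- simulate_group_experiment(
    group_effect_spec(base, n_per_group = 40, seed = 5))
  st <- group_experiment_stats(null_sim)
  expect_gt(st$tzp_count$p, 0.001)
  expect_lt(abs(st$tzp_count$percent_change), 15)

  tiny <- simulate_group_experiment(
    group_effect_spec(base, n_per_group = 2, seed = 6))
  st2 <- group_experiment_stats(tiny)
  expect_identical(st2$summaries$n[1:2], c(2L, 2L))

  eff <- simulate_group_experiment(
    group_effect_spec(base, n_per_group = 30, effect_tzp_count = -0.35,
                      seed = 7))
  st3 <- group_experiment_stats(eff)
  expect_lt(st3$tzp_count$p, 0.05)
  expect_gt(st3$tzp_count$percent_change, 20)
  # treated generative mean really is base * (1 + effect)
  expect_equal(eff$truth$treated$count_mean, 16 * 0.65)
})

test_that("truth records are JSON round-trippable without loss", {
  g <- generate_goc_2d(small_spec())
  p <- withr::local_tempfile(fileext = ".json")
  write_truth_json(g$truth, p)
  back <- read_truth_json(p)
  expect_equal(back$angles, g$truth$angles)
  expect_equal(back$n_tzp, g$truth$n_tzp)
  expect_equal(unname(unlist(back$center_um)), unname(g$truth$center_um))

  g3 <- generate_goc_3d(small_spec3d(), n_cells = 1)
  p3 <- withr::local_tempfile(fileext = ".json")
  write_truth_json(g3$truth, p3)
  back3 <- read_truth_json(p3)
  expect_equal(length(back3$filaments), length(g3$truth$filaments))
  expect_equal(back3$filaments[[1]]$points, g3$truth$filaments[[1]]$points)
  expect_equal(back3$cell_volumes, g3$truth$cell_volumes)
})
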