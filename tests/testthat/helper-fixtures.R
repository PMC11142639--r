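# Small geometries used across tests: fast to render, still several zona
# pixels wide at the default 0.1 um pixel.

small_spec <- function(...) {
  args <- list(oocyte_radius = 12, zona_thickness = 4, n_tzp = 12,
               tzp_width_mean = 0.1, noise_sd = 0,
               image_shape = c(448L, 448L), seed = 42L)
  args[names(list(...))] <- list(...)
  do.call(goc_spec, args)
}

small_spec3d <- function(...) {
  args <- list(oocyte_radius = 10, zona_thickness = 4, n_tzp = 4,
               voxel_size = c(0.3, 0.3, 0.3), seed = 7L)
  args[names(list(...))] <- list(...)
  do.call(goc_spec, args)
}

oocyte_of <- function(g) {
  oocyte_model(g$truth$center_um, g$truth$oocyte_radius,
               g$truth$zona_thickness)
}

# axis-aligned digitized ball mask (array dims symmetric, voxel h)
ball_mask <- function(r, h) {
  x <- seq(-r - 2 * h, r + 2 * h, by = h)
  n <- length(x)
  array(outer(outer(x^2, x^2, "+"), x^2, "+") <= r^2, c(n, n, n))
}

# digitized axis-aligned ellipsoid mask with semi-axes (a, b, c), voxel h
ellipsoid_mask <- function(a, b, c, h) {
  x1 <- seq(-a - 2 * h, a + 2 * h, by = h)
  x2 <- seq(-b - 2 * h, b + 2 * h, by = h)
  x3 <- seq(-c - 2 * h, c + 2 * h, by = h)
  q <- outer(outer((x1 / a)^2, (x2 / b)^2, "+"), (x3 / c)^2, "+")
  array(q <= 1, c(length(x1), length(x2), length(x3)))
}

# random jagged filament for property tests
random_filament <- function(n_pts = 8, scale = 5, parent = NA) {
  pts <- matrix(stats::rnorm(n_pts * 3, 0, scale), n_pts, 3)
  pts[, 1] <- pts[, 1] + 40  # keep it outside a radius-30 oocyte at origin
  filament(pts, radii = stats::runif(n_pts, 0.05, 0.3), parent_cell = parent)
}
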