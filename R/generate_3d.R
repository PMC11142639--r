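#' Generate a synthetic 3D GOC volume with ground truth
#'
#' Builds a 3D scene in the oocyte's coordinate frame (oocyte centre at the
#' origin): `n_cells` membrane-labelled ellipsoidal granulosa cell bodies
#' placed outside the zona pellucida shell, each carrying `spec$n_tzp`
#' filopodia-like filament polylines that run from the cell surface toward
#' the oocyte sphere (or away from it, for a `spec$away_fraction` share of
#' filaments).  The returned raster covers the cell bodies plus a margin
#' and is the GFP-style membrane channel used by [segment_cells()];
#' filaments are returned as exact polylines in the truth record, not
#' rasterized.
#'
#' The ground-truth volume of a cell is the volume enclosed by the *outer*
#' membrane surface (semi-axes plus half the membrane thickness), which is
#' the boundary an intensity threshold on the membrane label recovers.
#'
#' @param spec A [goc_spec()]; `n_tzp` is the number of filaments per cell
#'   and `voxel_size` the `(z, y, x)` rendering grid.
#' @param n_cells Number of granulosa cells (>= 0).
#' @param cell_centers Optional `n_cells x 3` matrix of `(x, y, z)` centres
#'   (um) in the oocyte frame; centres closer than the sum of the two cells'
#'   maximal radii are rejected as overlapping.
#' @param cell_radius_mean Mean ellipsoid semi-axis (um).
#' @param membrane_thickness Membrane shell thickness (um).
#' @param membrane_intensity,interior_intensity Membrane peak and cell
#'   interior intensities (a.u.).
#' @return A list with `volume` (a [goc_volume()]), `truth` (class
#'   `goc_truth`: filament polylines, per-cell volumes and centres, the
#'   raster origin `origin_um`, orientation classes) and `oocyte` (the
#'   [oocyte_model()] of the scene).
#' @export
generate_goc_3d <- function(spec, n_cells, cell_centers = NULL,
                            cell_radius_mean = 4,
                            membrane_thickness = 0.4,
                            membrane_intensity = 100,
                            interior_intensity = 15) {
  stopifnot(inherits(spec, "goc_spec"))
  if (n_cells < 0 || n_cells != round(n_cells))
    stop_field("n_cells", "must be a non-negative integer")
  r0 <- spec$oocyte_radius; zt <- spec$zona_thickness
  with_seed(spec$seed, {
    # cell geometry: axis-aligned ellipsoids with mild random anisotropy
    semi <- matrix(cell_radius_mean, max(n_cells, 1), 3) *
      matrix(stats::runif(3 * max(n_cells, 1), 0.85, 1.15), ncol = 3)
    semi <- semi[seq_len(n_cells), , drop = FALSE]
    if (is.null(cell_centers)) {
      if (n_cells > 0) {
        # spread directions on a cap of the sphere so cells never collide
        dirs <- seq_len(n_cells) - 1
        phi <- 2 * pi * dirs / max(n_cells, 1)
        # tilt successive cells slightly out of the equatorial plane
        elev <- 0.25 * sin(seq_len(n_cells))
        u <- cbind(cos(phi) * cos(elev), sin(phi) * cos(elev), sin(elev))
        rad <- r0 + zt + apply(semi, 1, max) + 0.5
        cell_centers <- u * rad
      } else cell_centers <- matrix(numeric(0), 0, 3)
    } else {
      cell_centers <- as.matrix(cell_centers)
      if (nrow(cell_centers) != n_cells || ncol(cell_centers) != 3)
        stop_field("cell_centers", "must be an n_cells x 3 (x, y, z) matrix")
    }
    if (n_cells >= 2) {
      rmax <- apply(semi, 1, max)
      for (i in seq_len(n_cells - 1)) for (j in (i + 1):n_cells) {
        d <- sqrt(sum((cell_centers[i, ] - cell_centers[j, ])^2))
        if (d < rmax[i] + rmax[j])
          stop(sprintf("cells %d and %d overlap: centre distance %.2f um < sum of radii %.2f um",
                       i, j, d, rmax[i] + rmax[j]))
      }
    }
    if (n_cells > 0) {
      dist0 <- sqrt(rowSums(cell_centers^2))
      if (any(dist0 - apply(semi, 1, max) < r0 + zt - 1e-9))
        stop("cell bodies must lie outside the zona pellucida shell")
    }

    # filaments: per cell, from the oocyte-facing surface point
    filaments <- list()
    classes <- character(0)
    if (n_cells > 0 && spec$n_tzp > 0) {
      for (ci in seq_len(n_cells)) {
        for (k in seq_len(spec$n_tzp)) {
          away <- stats::runif(1) < spec$away_fraction
          f <- make_tzp_filament(cell_centers[ci, ], semi[ci, ], r0,
                                 length_mean = spec$tzp_length_mean,
                                 length_sd = spec$tzp_length_sd,
                                 width = spec$tzp_width_mean,
                                 tortuosity = spec$tortuosity,
                                 away = away, parent_cell = ci)
          filaments <- c(filaments, list(f))
          classes <- c(classes, if (away) "away" else "toward")
        }
      }
    }

    # raster extent: cells plus margin, (z, y, x) axis order
    vol <- NULL; origin <- c(0, 0, 0)
    vs <- spec$voxel_size                     # (z, y, x)
    if (n_cells > 0) {
      outer_semi <- semi + membrane_thickness / 2
      lo <- apply(cell_centers - outer_semi, 2, min) - 2   # (x, y, z) um
      hi <- apply(cell_centers + outer_semi, 2, max) + 2
      nvox <- ceiling((hi - lo) / rev(vs)) + 1             # (x, y, z)
      arr <- array(spec$background_intensity,
                   c(nvox[3], nvox[2], nvox[1]))           # (z, y, x)
      zc <- lo[3] + (seq_len(nvox[3]) - 1) * vs[1]
      yc <- lo[2] + (seq_len(nvox[2]) - 1) * vs[2]
      xc <- lo[1] + (seq_len(nvox[1]) - 1) * vs[3]
      for (ci in seq_len(n_cells)) {
        a <- semi[ci, ]; ce <- cell_centers[ci, ]
        box_lo <- ce - a - membrane_thickness - 1
        box_hi <- ce + a + membrane_thickness + 1
        iz <- which(zc >= box_lo[3] & zc <= box_hi[3])
        iy <- which(yc >= box_lo[2] & yc <= box_hi[2])
        ix <- which(xc >= box_lo[1] & xc <= box_hi[1])
        if (!length(iz) || !length(iy) || !length(ix)) next
        # normalized ellipsoid coordinate q; q = 1 on the mid-membrane surface
        qx <- (xc[ix] - ce[1]) / a[1]
        qy <- (yc[iy] - ce[2]) / a[2]
        qz <- (zc[iz] - ce[3]) / a[3]
        Q2 <- outer(outer(qz^2, qy^2, "+"), qx^2, "+")     # (z, y, x)
        q <- sqrt(Q2)
        reff <- mean(a)                                    # um per unit q
        # soft-edged shell: half-max intensity exactly at +/- thickness/2
        # from the mid-membrane surface, so a half-max threshold recovers
        # the outer surface the truth volume is defined on
        aa <- min(vs)
        memb <- membrane_intensity *
          pmin(pmax((membrane_thickness / 2 - abs(q - 1) * reff) / aa + 0.5,
                    0), 1)
        interior <- ifelse(q < 1, interior_intensity, 0)
        sub <- arr[iz, iy, ix]
        arr[iz, iy, ix] <- pmax(sub, pmax(memb, interior))
      }
      if (spec$poisson_noise) {
        arr <- array(stats::rpois(length(arr), arr), dim(arr))
      }
      if (spec$noise_sd > 0)
        arr <- array(pmax(arr + stats::rnorm(length(arr), 0, spec$noise_sd), 0),
                     dim(arr))
      vol <- goc_volume(arr, vs, "gfp")
      origin <- lo                                          # (x, y, z) um
    }

    true_vol <- if (n_cells > 0)
      4 / 3 * pi * apply(semi + membrane_thickness / 2, 1, prod)
    else numeric(0)
    truth <- structure(list(
      kind = "goc_3d",
      n_cells = as.integer(n_cells),
      cell_centers = cell_centers,
      cell_semiaxes = semi,
      membrane_thickness = membrane_thickness,
      cell_volumes = true_vol,
      filaments = filaments,
      orientation_classes = classes,
      origin_um = origin,
      oocyte_radius = r0, zona_thickness = zt,
      seed = spec$seed, spec = unclass(spec)
    ), class = "goc_truth")
    list(volume = vol, truth = truth,
         oocyte = oocyte_model(center = c(0, 0, 0), radius = r0,
                               zona_thickness = zt))
  })
}

# Build one TZP-like polyline from a cell surface toward/away the oocyte.
# `center`, `semi` describe the parent ellipsoid; oocyte sphere of radius
# `r0` at the origin.  Tortuosity perturbs the step direction by seeded
# small-angle noise.  Coordinates (x, y, z) um.
make_tzp_filament <- function(center, semi, r0, length_mean, length_sd,
                              width, tortuosity, away = FALSE,
                              parent_cell = NA, step = 0.25) {
  u <- -center / sqrt(sum(center^2))          # unit vector toward the oocyte
  # ellipsoid radius along u, for the surface anchor point
  ru <- 1 / sqrt(sum((u / semi)^2))
  start <- center + u * ru
  L <- max(stats::rnorm(1, length_mean, length_sd), 4 * step)
  d_start <- sqrt(sum(start^2)) - r0
  if (!away) L <- min(L, max(d_start - 0.2, 2 * step))
  dir <- if (away) -u else u
  n_step <- max(ceiling(L / step), 2)
  if (tortuosity == 0) {
    pts <- matrix(start, n_step + 1, 3, byrow = TRUE) +
      outer(seq(0, L, length.out = n_step + 1), dir)
  } else {
    pts <- matrix(0, n_step + 1, 3)
    pts[1, ] <- start
    v <- dir
    for (i in seq_len(n_step)) {
      v <- v + tortuosity * stats::rnorm(3, 0, 0.3)
      v <- v / sqrt(sum(v^2))
      pts[i + 1, ] <- pts[i, ] + v * (L / n_step)
    }
  }
  filament(pts, radii = width / 2, parent_cell = parent_cell)
}
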