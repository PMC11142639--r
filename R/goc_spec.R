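#' Specification of a synthetic granulosa cell-oocyte complex
#'
#' A `goc_spec` collects every generative parameter of the synthetic
#' ground-truth model: the oocyte disk/sphere, the zona pellucida
#' annulus/shell the TZPs traverse, the TZP population (number, length,
#' width, tortuosity, orientation), staining intensities and the noise
#' model.  All lengths are in micrometres, intensities in arbitrary units.
#'
#' Geometry defaults follow the murine system the generator emulates: a
#' 30 um oocyte radius, a ~7 um zona pellucida, 0.1 um pixels in 2D and
#' 0.1 x 0.1 x 0.2 um (x, y, z) voxels in 3D.
#'
#' @param oocyte_radius Oocyte radius (um).
#' @param zona_thickness Zona pellucida thickness (um).
#' @param n_tzp Number of transzonal projections.
#' @param tzp_length_mean,tzp_length_sd Filament length distribution (um);
#'   used by the 3D/filament generators.
#' @param tzp_width_mean Mean filament diameter (um).
#' @param tzp_intensity Peak TZP staining intensity (a.u.).
#' @param cytoplasm_intensity Oocyte cytoplasm intensity (a.u.); this is the
#'   signal the counting rule uses as its background reference.
#' @param background_intensity Extracellular background (a.u.).
#' @param zona_intensity Faint zona matrix signal (a.u.).
#' @param cortex_intensity Peak intensity of the F-actin-rich oocyte cortex
#'   ring (a.u.).
#' @param noise_sd Gaussian read-noise standard deviation (a.u.).
#' @param poisson_noise If `TRUE`, apply Poisson shot noise before the
#'   Gaussian read noise.
#' @param tortuosity Dimensionless >= 0; scale of the seeded small-angle
#'   random-walk perturbation applied to filament polylines (0 = straight).
#' @param away_fraction Fraction of filaments oriented away from the oocyte
#'   (tip farther from the surface than the origin), in \[0, 1\].
#' @param pixel_size 2D pixel size (um).
#' @param voxel_size 3D voxel size as `(z, y, x)` (um).
#' @param image_shape 2D image shape `(rows, cols)` in pixels; the 3D
#'   generator chooses its own extent from the scene.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class `goc_spec` (a validated named list).
#' @examples
#' spec <- goc_spec(n_tzp = 12, noise_sd = 0)
#' spec$oocyte_radius
#' @export
goc_spec <- function(oocyte_radius = 30, zona_thickness = 7, n_tzp = 40,
                     tzp_length_mean = 4.6, tzp_length_sd = 0.8,
                     tzp_width_mean = 0.4, tzp_intensity = 100,
                     cytoplasm_intensity = 40, background_intensity = 5,
                     zona_intensity = 8, cortex_intensity = 90,
                     noise_sd = 0, poisson_noise = FALSE,
                     tortuosity = 0, away_fraction = 0,
                     pixel_size = 0.1, voxel_size = c(0.2, 0.1, 0.1),
                     image_shape = c(1024L, 1024L), seed = 1L) {
  check_scalar(oocyte_radius, "oocyte_radius", positive = TRUE)
  check_scalar(zona_thickness, "zona_thickness", positive = TRUE)
  check_scalar(n_tzp, "n_tzp", nonneg = TRUE)
  if (n_tzp != round(n_tzp)) stop_field("n_tzp", "must be an integer count")
  check_scalar(tzp_length_mean, "tzp_length_mean", positive = TRUE)
  check_scalar(tzp_length_sd, "tzp_length_sd", nonneg = TRUE)
  check_scalar(tzp_width_mean, "tzp_width_mean", positive = TRUE)
  check_scalar(tzp_intensity, "tzp_intensity", positive = TRUE)
  check_scalar(cytoplasm_intensity, "cytoplasm_intensity", nonneg = TRUE)
  check_scalar(background_intensity, "background_intensity", nonneg = TRUE)
  check_scalar(zona_intensity, "zona_intensity", nonneg = TRUE)
  check_scalar(cortex_intensity, "cortex_intensity", nonneg = TRUE)
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(tortuosity, "tortuosity", nonneg = TRUE)
  check_scalar(away_fraction, "away_fraction")
  if (away_fraction < 0 || away_fraction > 1)
    stop_field("away_fraction", "must lie in [0, 1]")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop_field("voxel_size", "must be three positive (z, y, x) sizes")
  if (length(image_shape) != 2L || any(image_shape < 8))
    stop_field("image_shape", "must be two pixel counts >= 8")
  if (tzp_intensity <= cytoplasm_intensity && n_tzp > 0)
    stop_field("tzp_intensity",
               "must exceed cytoplasm_intensity for detectable contrast")
  check_scalar(seed, "seed")
  structure(list(
    oocyte_radius = oocyte_radius, zona_thickness = zona_thickness,
    n_tzp = as.integer(n_tzp),
    tzp_length_mean = tzp_length_mean, tzp_length_sd = tzp_length_sd,
    tzp_width_mean = tzp_width_mean, tzp_intensity = tzp_intensity,
    cytoplasm_intensity = cytoplasm_intensity,
    background_intensity = background_intensity,
    zona_intensity = zona_intensity, cortex_intensity = cortex_intensity,
    noise_sd = noise_sd, poisson_noise = isTRUE(poisson_noise),
    tortuosity = tortuosity, away_fraction = away_fraction,
    pixel_size = pixel_size, voxel_size = as.numeric(voxel_size),
    image_shape = as.integer(image_shape), seed = as.integer(seed)
  ), class = "goc_spec")
}

#' @export
print.goc_spec <- function(x, ...) {
  cat("Synthetic GOC specification\n")
  cat(sprintf("  oocyte radius %.1f um, zona %.1f um, %d TZPs\n",
              x$oocyte_radius, x$zona_thickness, x$n_tzp))
  cat(sprintf("  TZP length %.2f +/- %.2f um, width %.2f um, tortuosity %.2f, away fraction %.2f\n",
              x$tzp_length_mean, x$tzp_length_sd, x$tzp_width_mean,
              x$tortuosity, x$away_fraction))
  cat(sprintf("  intensities (a.u.): tzp %.0f, cytoplasm %.0f, zona %.0f, background %.0f; noise sd %.1f\n",
              x$tzp_intensity, x$cytoplasm_intensity, x$zona_intensity,
              x$background_intensity, x$noise_sd))
  cat(sprintf("  pixel %.2f um; voxel (%.2f, %.2f, %.2f) um; seed %d\n",
              x$pixel_size, x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$seed))
  invisible(x)
}

#' Specification of a synthetic two-group experiment
#'
#' Describes a control vs treated contrast in which the treated group's
#' generative parameters are the control parameters scaled by
#' `(1 + effect)`.  A negative effect is a reduction, e.g.
#' `effect_tzp_count = -0.35` imposes a 35% lower mean TZP-per-cell count.
#'
#' @param base A [goc_spec()] describing the control group.
#' @param n_per_group Cells (specimens) per group, >= 2.
#' @param effect_tzp_count,effect_tzp_length,effect_cell_volume Relative
#'   changes applied to the treated group's mean TZP count per cell, mean
#'   TZP length and mean cell volume; each must satisfy `|effect| < 1`.
#' @param cell_volume_mean Control-group mean cell volume (um^3).
#' @param cell_volume_cv Coefficient of variation of the lognormal cell
#'   volume distribution.
#' @param seed Master seed; per-specimen seeds are derived from it.
#'
#' @return An object of class `group_effect_spec`.
#' @export
group_effect_spec <- function(base = goc_spec(n_tzp = 16),
                              n_per_group = 25,
                              effect_tzp_count = 0,
                              effect_tzp_length = 0,
                              effect_cell_volume = 0,
                              cell_volume_mean = 323.2,
                              cell_volume_cv = 0.5,
                              seed = 1L) {
  stopifnot(inherits(base, "goc_spec"))
  check_scalar(n_per_group, "n_per_group")
  if (n_per_group < 2) stop_field("n_per_group", "must be >= 2")
  for (e in c("effect_tzp_count", "effect_tzp_length", "effect_cell_volume")) {
    v <- get(e)
    check_scalar(v, e)
    if (abs(v) >= 1) stop_field(e, "must satisfy |effect| < 1")
  }
  check_scalar(cell_volume_mean, "cell_volume_mean", positive = TRUE)
  check_scalar(cell_volume_cv, "cell_volume_cv", positive = TRUE)
  check_scalar(seed, "seed")
  structure(list(base = base, n_per_group = as.integer(n_per_group),
                 effect_tzp_count = effect_tzp_count,
                 effect_tzp_length = effect_tzp_length,
                 effect_cell_volume = effect_cell_volume,
                 cell_volume_mean = cell_volume_mean,
                 cell_volume_cv = cell_volume_cv,
                 seed = as.integer(seed)),
            class = "group_effect_spec")
}
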