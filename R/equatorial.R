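#' Oocyte reference model
#'
#' Idealizes the oocyte as a circle (2D, centre `(y, x)`) or sphere (3D,
#' centre `(x, y, z)`) of radius `radius`, wrapped by a zona pellucida of
#' thickness `zona_thickness`.  All distance-to-surface and mid-zona
#' computations refer to this model.
#'
#' @param center Numeric centre, length 2 `(y, x)` or 3 `(x, y, z)`, um.
#' @param radius Oocyte radius (um).
#' @param zona_thickness Zona thickness (um).
#' @return An object of class `oocyte_model`.
#' @export
oocyte_model <- function(center, radius, zona_thickness = 7) {
  if (!length(center) %in% c(2L, 3L)) stop("`center` must have length 2 or 3")
  check_scalar(radius, "radius", positive = TRUE)
  check_scalar(zona_thickness, "zona_thickness", positive = TRUE)
  structure(list(center = as.numeric(center), radius = radius,
                 zona_thickness = zona_thickness),
            class = "oocyte_model")
}

#' @export
print.oocyte_model <- function(x, ...) {
  cat(sprintf("oocyte_model: centre (%s) um, radius %.2f um, zona %.2f um\n",
              paste(sprintf("%.2f", x$center), collapse = ", "),
              x$radius, x$zona_thickness))
  invisible(x)
}

#' Estimate the oocyte-cytoplasm background level
#'
#' The counting rule scores a profile sample as a TZP only if it exceeds
#' the background level of the oocyte cytoplasm.  That level is summarized
#' over an interior disk of radius `0.7 * radius` centred on the oocyte -
#' comfortably inside the bright F-actin cortex - using the median (robust
#' to organellar texture) or the mean.
#'
#' @param image A [goc_image()].
#' @param oocyte An [oocyte_model()] with a 2D `(y, x)` centre.
#' @param statistic `"median"` (default) or `"mean"`.
#' @param interior_fraction Radius fraction of the interior disk.
#' @return Scalar background intensity (a.u.).
#' @export
estimate_background <- function(image, oocyte,
                                statistic = c("median", "mean"),
                                interior_fraction = 0.7) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(image, "goc_image"), inherits(oocyte, "oocyte_model"))
  h <- image$pixel_size
  yy <- (seq_len(nrow(image$intensities)) - 1) * h - oocyte$center[1]
  xx <- (seq_len(ncol(image$intensities)) - 1) * h - oocyte$center[2]
  R <- sqrt(outer(yy^2, xx^2, "+"))
  inside <- R <= interior_fraction * oocyte$radius
  if (!any(inside))
    stop("oocyte interior ROI is empty (oocyte outside the image?)")
  vals <- image$intensities[inside]
  if (statistic == "median") stats::median(vals) else mean(vals)
}

#' Sample the circular intensity profile at mid-zona
#'
#' Draws the closed circle of radius `radius + zona_thickness / 2` around
#' the oocyte centre and samples the image by bilinear interpolation at
#' uniform arc steps, emulating the segmented circle drawn through the
#' middle of the zona pellucida along which TZP crossings appear as
#' intensity peaks.
#'
#' @param image A [goc_image()].
#' @param oocyte An [oocyte_model()] with a 2D `(y, x)` centre.
#' @param sampling_step Arc-length step (um); default one pixel.
#' @return An object of class `radial_profile` with `samples`,
#'   `arc_positions` (um), `source_radius` and `circular = TRUE`.
#' @export
extract_equatorial_profile <- function(image, oocyte,
                                       sampling_step = image$pixel_size) {
  stopifnot(inherits(image, "goc_image"), inherits(oocyte, "oocyte_model"))
  check_scalar(sampling_step, "sampling_step", positive = TRUE)
  h <- image$pixel_size
  rc <- oocyte$radius + oocyte$zona_thickness / 2
  n <- ceiling(2 * pi * rc / sampling_step)
  if (n < 8) stop("profile would have fewer than 8 samples")
  theta <- 2 * pi * (seq_len(n) - 1) / n
  py <- (oocyte$center[1] + rc * sin(theta)) / h + 1
  px <- (oocyte$center[2] + rc * cos(theta)) / h + 1
  if (any(py < 1 | py > nrow(image$intensities) |
          px < 1 | px > ncol(image$intensities)))
    stop("mid-zona circle exits the image bounds")
  structure(list(samples = bilinear_sample(image$intensities, py, px),
                 arc_positions = rc * theta,
                 circular = TRUE,
                 source_radius = rc),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile: %d samples on a closed circle of radius %.2f um (arc step %.3f um)\n",
              length(x$samples), x$source_radius,
              diff(x$arc_positions[1:2])))
  invisible(x)
}

#' Count TZP peaks on a circular profile
#'
#' Applies the counting rule: a sample is a TZP peak iff its value is above
#' the cytoplasm background *and* strictly higher than each of its two
#' immediate neighbours, with circular indexing (the first and last samples
#' are adjacent; plateaus are not counted).  An optional circular boxcar
#' smoother (odd `smooth_window` >= 3) can be applied first; the default
#' applies none.
#'
#' @param profile A `radial_profile` (or bare numeric vector, treated as
#'   circular).
#' @param background Scalar background level, from [estimate_background()].
#' @param smooth_window Circular boxcar width in samples (0 or 1 = none).
#' @return An object of class `tzp_count` with `raw_count`, `peak_indices`,
#'   `background` and the (possibly smoothed) `samples`.
#' @export
count_tzp_peaks <- function(profile, background, smooth_window = 0) {
  s <- if (inherits(profile, "radial_profile")) profile$samples
       else as.numeric(profile)
  n <- length(s)
  if (n < 3) stop("profile must have at least 3 samples")
  check_scalar(background, "background")
  if (smooth_window >= 2) {
    w <- as.integer(smooth_window)
    if (w %% 2L == 0L) w <- w + 1L
    half <- (w - 1L) %/% 2L
    ext <- c(s[(n - half + 1):n], s, s[1:half])
    s <- as.numeric(stats::filter(ext, rep(1 / w, w), sides = 2))[(half + 1):(half + n)]
  }
  left <- s[c(n, seq_len(n - 1))]
  right <- s[c(seq_len(n - 1) + 1, 1)]
  peaks <- which(s > background & s > left & s > right)
  structure(list(raw_count = length(peaks), peak_indices = peaks,
                 background = background, samples = s),
            class = "tzp_count")
}

#' Normalize a TZP count to the oocyte diameter
#'
#' Counts from differently sized oocytes are compared per micrometre of
#' oocyte diameter.
#'
#' @param raw_count Non-negative count.
#' @param oocyte_diameter Oocyte diameter (um), > 0.
#' @return Count per um of diameter.
#' @examples
#' normalize_tzp_count(120, 60)  # 2 TZPs per um
#' @export
normalize_tzp_count <- function(raw_count, oocyte_diameter) {
  check_scalar(raw_count, "raw_count", nonneg = TRUE)
  check_scalar(oocyte_diameter, "oocyte_diameter")
  if (oocyte_diameter <= 0)
    stop_field("oocyte_diameter", "must be > 0")
  raw_count / oocyte_diameter
}

#' Full equatorial TZP count on one image
#'
#' Convenience wrapper running background estimation, mid-zona profile
#' extraction, peak counting and diameter normalization in one call.
#'
#' @inheritParams extract_equatorial_profile
#' @inheritParams count_tzp_peaks
#' @param background_statistic Passed to [estimate_background()].
#' @return A `tzp_count` with additional fields `normalized_count`
#'   (per um of oocyte diameter), `oocyte_diameter` and `n_samples`.
#' @export
count_tzp <- function(image, oocyte, sampling_step = image$pixel_size,
                      smooth_window = 0,
                      background_statistic = c("median", "mean")) {
  bg <- estimate_background(image, oocyte,
                            statistic = match.arg(background_statistic))
  prof <- extract_equatorial_profile(image, oocyte, sampling_step)
  res <- count_tzp_peaks(prof, bg, smooth_window)
  res$oocyte_diameter <- 2 * oocyte$radius
  res$normalized_count <- normalize_tzp_count(res$raw_count,
                                              res$oocyte_diameter)
  res$n_samples <- length(prof$samples)
  res
}

#' @export
print.tzp_count <- function(x, ...) {
  cat(sprintf("tzp_count: %d peaks above background %.2f", x$raw_count,
              x$background))
  if (!is.null(x$normalized_count))
    cat(sprintf(" (%.3f per um of oocyte diameter)", x$normalized_count))
  cat("\n")
  invisible(x)
}

#' Least-squares circle fit to the oocyte cortex
#'
#' Algebraic (Kasa) circle fit to the brightest pixels of the image, which
#' in an F-actin-stained equatorial section trace the oocyte cortex.  Used
#' when no centre/radius is supplied by the caller.
#'
#' @param image A [goc_image()].
#' @param intensity_quantile Pixels above this intensity quantile enter the
#'   fit.
#' @param zona_thickness Zona thickness passed through to the returned
#'   model (um).
#' @return An [oocyte_model()] with a 2D `(y, x)` centre.
#' @export
fit_oocyte_circle <- function(image, intensity_quantile = 0.995,
                              zona_thickness = 7) {
  stopifnot(inherits(image, "goc_image"))
  h <- image$pixel_size
  thr <- stats::quantile(image$intensities, intensity_quantile)
  idx <- which(image$intensities >= thr, arr.ind = TRUE)
  if (nrow(idx) < 10) stop("too few bright pixels for a circle fit")
  y <- (idx[, 1] - 1) * h; x <- (idx[, 2] - 1) * h
  # Kasa: minimize ||x^2 + y^2 - 2ax - 2by - c||
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- stats::lm.fit(A, b)$coefficients
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  oocyte_model(center = c(sol[2], sol[1]), radius = unname(r),
               zona_thickness = zona_thickness)
}
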