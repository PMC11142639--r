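#' Generate a synthetic equatorial GOC section with ground truth
#'
#' Renders the equatorial confocal plane of a granulosa cell-oocyte complex
#' as an F-actin-style image: an oocyte disk of cytoplasm signal with a
#' bright cortical ring, a faint zona pellucida annulus, and `n_tzp`
#' radial filopodia-like projections crossing the zona at distinct angles.
#' Filaments are rendered as capsules (segments with a Gaussian
#' cross-section of sigma = width/2) blended by maximum, so each projection
#' produces one unimodal bump of peak intensity `tzp_intensity` on the
#' mid-zona circle.  Optional Poisson shot noise and Gaussian read noise
#' are applied last.  Identical spec + seed gives bit-identical output.
#'
#' TZP angles are drawn as jittered regular positions, which bounds the
#' minimum angular separation at `0.3 * 2 * pi / n_tzp`; a spec whose
#' implied separation at the mid-zona radius falls below 2 pixels is
#' rejected because adjacent intensity peaks would be unresolvable.
#'
#' @param spec A [goc_spec()].
#' @return A list with elements `image` (a [goc_image()]) and `truth` (a
#'   `goc_truth` list recording the count, per-filament angles, radial
#'   extents, widths and polylines, plus the generating parameters).
#' @examples
#' g <- generate_goc_2d(goc_spec(oocyte_radius = 12, zona_thickness = 4,
#'                               n_tzp = 8, image_shape = c(384, 384)))
#' g$truth$n_tzp
#' @export
generate_goc_2d <- function(spec) {
  stopifnot(inherits(spec, "goc_spec"))
  h <- spec$pixel_size
  shp <- spec$image_shape
  r0 <- spec$oocyte_radius; zt <- spec$zona_thickness
  extent <- c(shp[1], shp[2]) * h
  if (any(2 * (r0 + zt + 5) > extent))
    stop("image too small: oocyte + zona + 5 um margin exceeds image bounds")
  rc <- r0 + zt / 2
  if (spec$n_tzp > 0) {
    min_sep_um <- 0.3 * 2 * pi / spec$n_tzp * rc
    if (min_sep_um < 2 * h)
      stop(sprintf(
        "n_tzp = %d gives a minimum angular separation of %.2f um (< 2 pixels) at the mid-zona radius; peaks would be unresolvable",
        spec$n_tzp, min_sep_um))
  }
  with_seed(spec$seed, {
    cy <- (shp[1] - 1) / 2 * h; cx <- (shp[2] - 1) / 2 * h
    yy <- (seq_len(shp[1]) - 1) * h - cy
    xx <- (seq_len(shp[2]) - 1) * h - cx
    R <- sqrt(outer(yy^2, xx^2, "+"))
    soft <- function(d) pmin(pmax(d / h + 0.5, 0), 1)  # 1-px anti-aliased edge
    img <- spec$background_intensity +
      (spec$cytoplasm_intensity - spec$background_intensity) * soft(r0 - R) +
      (spec$zona_intensity - spec$background_intensity) *
        soft(R - r0) * soft(r0 + zt - R)
    if (spec$cortex_intensity > 0)
      img <- pmax(img, spec$cortex_intensity * exp(-(R - r0)^2 / (2 * 0.3^2)))
    angles <- numeric(0)
    if (spec$n_tzp > 0) {
      n <- spec$n_tzp
      angles <- sort((2 * pi * (0:(n - 1) + stats::runif(n, -0.35, 0.35)) / n) %% (2 * pi))
      sw <- spec$tzp_width_mean / 2
      r_in <- r0 - 0.5; r_out <- r0 + zt + 0.5
      for (th in angles) {
        p0 <- c(sin(th), cos(th)) * r_in   # (y, x) um relative to centre
        p1 <- c(sin(th), cos(th)) * r_out
        iy <- which(yy >= min(p0[1], p1[1]) - 4 * sw &
                    yy <= max(p0[1], p1[1]) + 4 * sw)
        ix <- which(xx >= min(p0[2], p1[2]) - 4 * sw &
                    xx <= max(p0[2], p1[2]) + 4 * sw)
        Y <- matrix(yy[iy], length(iy), length(ix))
        X <- matrix(xx[ix], length(iy), length(ix), byrow = TRUE)
        vy <- p1[1] - p0[1]; vx <- p1[2] - p0[2]; L2 <- vx^2 + vy^2
        tt <- pmin(pmax(((X - p0[2]) * vx + (Y - p0[1]) * vy) / L2, 0), 1)
        d2 <- (X - (p0[2] + tt * vx))^2 + (Y - (p0[1] + tt * vy))^2
        img[iy, ix] <- pmax(img[iy, ix],
                            spec$tzp_intensity * exp(-d2 / (2 * sw^2)))
      }
    }
    if (spec$poisson_noise) img <- stats::rpois(length(img), img)
    if (spec$noise_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sd)
    img <- matrix(pmax(img, 0), shp[1], shp[2])
    truth <- structure(list(
      kind = "goc_2d",
      n_tzp = spec$n_tzp,
      angles = angles,
      r_inner = if (spec$n_tzp > 0) r0 - 0.5 else numeric(0),
      r_outer = if (spec$n_tzp > 0) r0 + zt + 0.5 else numeric(0),
      widths = rep(spec$tzp_width_mean, spec$n_tzp),
      center_um = c(y = cy, x = cx),
      oocyte_radius = r0, zona_thickness = zt,
      seed = spec$seed, spec = unclass(spec)
    ), class = "goc_truth")
    list(image = goc_image(img, h, "phalloidin"), truth = truth)
  })
}

#' Serialize and restore ground-truth records
#'
#' Truth objects round-trip through JSON without loss of geometry (numbers
#' are written at full precision).
#'
#' @param truth A `goc_truth` object.
#' @param path JSON path.
#' @return `write_truth_json()`: `path`, invisibly; `read_truth_json()`: the
#'   restored `goc_truth`.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", force = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  if (!is.null(x$filaments) && is.list(x$filaments))
    x$filaments <- lapply(x$filaments, function(f) {
      pts <- f$points
      if (!is.matrix(pts)) pts <- matrix(unlist(pts), ncol = 3, byrow = TRUE)
      pc <- f$parent_cell
      filament(pts, unlist(f$radii),
               if (is.null(pc) || length(pc) == 0) NA else pc)
    })
  structure(x, class = "goc_truth")
}
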