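#' Filament arc length
#'
#' Sum of Euclidean segment lengths of the polyline; 0 for a single-point
#' filament.
#'
#' @param f A [filament()].
#' @return Length in um.
#' @examples
#' filament_length(filament(rbind(c(0, 0, 0), c(3, 4, 0))))  # 5
#' @export
filament_length <- function(f) {
  stopifnot(inherits(f, "filament"))
  p <- f$points
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Mean filament width
#'
#' Mean over points of twice the point radius, with each point's diameter
#' floored at `min_diameter` (0.1 um, the tracing minimum).
#'
#' @param f A [filament()].
#' @param min_diameter Per-point diameter floor (um).
#' @return Mean width in um.
#' @export
filament_mean_width <- function(f, min_diameter = 0.1) {
  stopifnot(inherits(f, "filament"))
  if (is.null(f$radii)) stop("filament has no radii")
  mean(pmax(2 * f$radii, min_diameter))
}

#' Discretize a filament into spots
#'
#' Places spots along the polyline at arc-length multiples of `spacing`,
#' always including the start and the tip (the final interval may be
#' shorter than `spacing`).  Mirrors the spot discretization used to read
#' out per-position distances along traced TZPs.
#'
#' @param f A [filament()].
#' @param spacing Arc-length spacing (um), > 0; default 0.2 um (the
#'   acquisition z-step).
#' @return An object of class `spot_chain`: `spots` (n x 3 matrix, um),
#'   `arc` (arc positions, um) and `spacing`.
#' @export
filament_to_spots <- function(f, spacing = 0.2) {
  stopifnot(inherits(f, "filament"))
  check_scalar(spacing, "spacing", positive = TRUE)
  p <- f$points
  L <- filament_length(f)
  s_targets <- seq(0, L, by = spacing)
  if (L - s_targets[length(s_targets)] > 1e-12) s_targets <- c(s_targets, L)
  if (length(s_targets) < 2) s_targets <- c(0, L)
  if (nrow(p) < 2) {
    spots <- p[rep(1, length(s_targets)), , drop = FALSE]
  } else {
    seg <- p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE]
    seg_len <- sqrt(rowSums(seg^2))
    cum <- c(0, cumsum(seg_len))
    spots <- t(vapply(s_targets, function(s) {
      i <- max(which(cum <= s + 1e-12))
      i <- min(i, nrow(p) - 1)
      t0 <- if (seg_len[i] > 0) (s - cum[i]) / seg_len[i] else 0
      p[i, ] + pmin(pmax(t0, 0), 1) * seg[i, ]
    }, numeric(3)))
  }
  structure(list(spots = spots, arc = s_targets, spacing = spacing),
            class = "spot_chain")
}

#' Signed distance to the oocyte surface
#'
#' For the sphere model: `||p - centre|| - radius`; positive outside the
#' oocyte, negative inside, zero on the surface.
#'
#' @param p A length-3 `(x, y, z)` point or an n x 3 matrix (um).
#' @param oocyte An [oocyte_model()] with a 3D centre.
#' @return Signed distance(s) in um.
#' @export
distance_to_surface <- function(p, oocyte) {
  stopifnot(inherits(oocyte, "oocyte_model"))
  if (length(oocyte$center) != 3)
    stop("distance_to_surface needs a 3D oocyte model")
  p <- if (is.matrix(p)) p else matrix(p, 1)
  sqrt(rowSums(sweep(p, 2, oocyte$center)^2)) - oocyte$radius
}

#' Orientation statistic and full per-filament metrics
#'
#' Computes the orientation difference
#' `delta = distance_to_surface(start) - distance_to_surface(tip)`: a
#' positive delta means the tip is closer to the oocyte than the origin
#' ("toward"), a negative delta that it is farther ("away"); exactly zero
#' is classed "neutral".  Also returns arc length, mean width and the two
#' endpoint distances.
#'
#' @param f A [filament()].
#' @param oocyte An [oocyte_model()] (3D) in the same frame as `f`.
#' @return A one-row data.frame: `parent_cell`, `length`, `mean_width`,
#'   `d_start`, `d_tip`, `delta`, `orientation_class`.
#' @export
orientation_delta <- function(f, oocyte) {
  stopifnot(inherits(f, "filament"))
  d_start <- distance_to_surface(f$points[1, ], oocyte)
  d_tip <- distance_to_surface(f$points[nrow(f$points), ], oocyte)
  delta <- d_start - d_tip
  cls <- if (delta > 0) "toward" else if (delta < 0) "away" else "neutral"
  data.frame(parent_cell = if (is.null(f$parent_cell)) NA else f$parent_cell,
             length = filament_length(f),
             mean_width = filament_mean_width(f),
             d_start = d_start, d_tip = d_tip, delta = delta,
             orientation_class = cls, stringsAsFactors = FALSE)
}

#' Measure a collection of filaments
#'
#' @param filaments List of [filament()] objects.
#' @param oocyte An [oocyte_model()] (3D).
#' @return A data.frame with one row per filament (see
#'   [orientation_delta()]).
#' @export
measure_filaments <- function(filaments, oocyte) {
  if (!length(filaments))
    return(data.frame(parent_cell = character(0), length = numeric(0),
                      mean_width = numeric(0), d_start = numeric(0),
                      d_tip = numeric(0), delta = numeric(0),
                      orientation_class = character(0)))
  do.call(rbind, lapply(filaments, orientation_delta, oocyte = oocyte))
}

#' Per-cell filament summaries
#'
#' Aggregates filament metrics by parent cell: TZP count, mean length,
#' mean width and the away-proportion
#' `#away / (#toward + #away + #neutral)`.  Cells listed in `cells` but
#' owning no filament get a count of 0 and missing (`NA`) means and
#' proportions - an empty cell has no defined mean or orientation.
#'
#' @param metrics Data.frame from [measure_filaments()]; every row must
#'   have a non-missing `parent_cell`.
#' @param cells Optional vector of all cell labels to report (defaults to
#'   the labels present).
#' @return A data.frame: `cell`, `n_tzp`, `mean_length`, `mean_width`,
#'   `away_proportion`.
#' @export
aggregate_per_cell <- function(metrics, cells = NULL) {
  if (nrow(metrics) && any(is.na(metrics$parent_cell)))
    stop("orphan filaments: every filament needs a parent_cell")
  labs <- if (is.null(cells)) unique(metrics$parent_cell) else cells
  out <- lapply(labs, function(lb) {
    m <- metrics[!is.na(metrics$parent_cell) & metrics$parent_cell == lb, ,
                 drop = FALSE]
    n <- nrow(m)
    data.frame(cell = lb, n_tzp = n,
               mean_length = if (n) mean(m$length) else NA_real_,
               mean_width = if (n) mean(m$mean_width) else NA_real_,
               away_proportion = if (n) mean(m$orientation_class == "away")
                                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Least-squares sphere fit
#'
#' Algebraic (Kasa) sphere fit to a 3D point cloud, e.g. cortical surface
#' points, for building an [oocyte_model()] when none is supplied.
#'
#' @param points n x 3 `(x, y, z)` matrix (um), n >= 4.
#' @param zona_thickness Zona thickness for the returned model (um).
#' @return An [oocyte_model()].
#' @export
fit_oocyte_sphere <- function(points, zona_thickness = 7) {
  points <- as.matrix(points)
  if (nrow(points) < 4) stop("need at least 4 points for a sphere fit")
  A <- cbind(2 * points, 1)
  b <- rowSums(points^2)
  sol <- stats::lm.fit(A, b)$coefficients
  r <- sqrt(sol[4] + sum(sol[1:3]^2))
  oocyte_model(center = unname(sol[1:3]), radius = unname(r),
               zona_thickness = zona_thickness)
}
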