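#' Segment membrane-labelled cells in a 3D volume
#'
#' Thresholds the membrane channel, optionally applies a binary closing to
#' seal small gaps, floods enclosed interiors (any non-membrane region not
#' connected to the volume border), labels the 3D connected components
#' (6-connectivity) and discards components whose physical volume is below
#' `min_volume` (exclusive, default 100 um^3).  Touching cells merge into
#' one label; well-separated bodies are recovered one label each.
#'
#' @param volume A [goc_volume()] (membrane channel).
#' @param intensity_threshold Threshold on the membrane signal (a.u.); must
#'   lie within the data range.
#' @param min_volume Minimum cell volume kept (um^3), exclusive filter.
#' @param closing_steps Binary closing iterations (6-neighbourhood), 0 = none.
#' @return A list of `cell_segment` objects, each with `label`,
#'   `voxel_idx` (linear indices into the volume), `n_voxels`, `volume`
#'   (um^3), `surface_area` (um^2) and `sphericity`.
#' @export
segment_cells <- function(volume, intensity_threshold, min_volume = 100,
                          closing_steps = 0) {
  stopifnot(inherits(volume, "goc_volume"))
  a <- volume$intensities
  if (!length(a)) stop("empty volume")
  rng <- range(a)
  if (intensity_threshold < rng[1] || intensity_threshold > rng[2])
    stop(sprintf("intensity_threshold %.3g outside the data range [%.3g, %.3g]",
                 intensity_threshold, rng[1], rng[2]))
  mask <- a > intensity_threshold
  if (closing_steps > 0) {
    m <- mask
    for (i in seq_len(closing_steps)) m <- dilate6(m)
    for (i in seq_len(closing_steps)) m <- erode6(m)
    mask <- m
  }
  # fill enclosed interiors: background components not touching the border
  bglab <- label_components3d(!mask)
  d <- dim(mask)
  border <- unique(c(bglab[1, , ], bglab[d[1], , ], bglab[, 1, ],
                     bglab[, d[2], ], bglab[, , 1], bglab[, , d[3]]))
  border <- border[border > 0]
  enclosed <- bglab > 0 & !(bglab %in% border)
  filled <- mask | enclosed
  lab <- label_components3d(filled)
  vv <- prod(volume$voxel_size)
  segs <- list()
  if (max(lab) > 0) {
    counts <- tabulate(lab, nbins = max(lab))
    # exclusive "<" filter: drop components with volume strictly below min_volume
    keep <- which(!(counts * vv < min_volume))
    lbl <- 0L
    for (k in keep) {
      lbl <- lbl + 1L
      idx <- which(lab == k)
      m <- measure_mask(lab == k, volume$voxel_size)
      segs[[lbl]] <- structure(list(label = lbl, voxel_idx = idx,
                                    n_voxels = counts[k],
                                    volume = m$volume,
                                    surface_area = m$surface_area,
                                    sphericity = m$sphericity),
                               class = "cell_segment")
    }
  }
  segs
}

#' @export
print.cell_segment <- function(x, ...) {
  cat(sprintf("cell_segment %s: V = %.1f um^3, A = %.1f um^2, sphericity %.3f\n",
              x$label, x$volume, x$surface_area, x$sphericity))
  invisible(x)
}

#' Measure volume, surface area and sphericity of a segment
#'
#' Volume is voxel count times voxel volume.  Surface area comes from a
#' marching-tetrahedra iso-surface of the 3^3 box-mollified binary mask
#' (naive voxel-face counting overestimates the area of oblique surfaces
#' by tens of percent and is not used).  Sphericity is the Wadell ratio
#' `psi = pi^(1/3) (6 V)^(2/3) / A`, 1 for a sphere; discretization can
#' push it a few percent above 1 for near-spheres.
#'
#' @param segment A `cell_segment` from [segment_cells()], or a logical 3D
#'   mask.
#' @param volume The [goc_volume()] the segment indexes into (omit when
#'   passing a mask).
#' @param voxel_size `(z, y, x)` voxel sizes (um), required with a mask.
#' @return A list with `volume` (um^3), `surface_area` (um^2), `sphericity`.
#' @examples
#' # digitized sphere: sphericity close to 1
#' h <- 0.4; r <- 3
#' x <- seq(-r - 2 * h, r + 2 * h, by = h)
#' m <- array(outer(outer(x^2, x^2, "+"), x^2, "+") <= r^2,
#'            c(length(x), length(x), length(x)))
#' measure_cell(m, voxel_size = c(h, h, h))$sphericity
#' @export
measure_cell <- function(segment, volume = NULL, voxel_size = NULL) {
  if (inherits(segment, "cell_segment")) {
    if (is.null(volume) && is.null(voxel_size))
      stop("supply `volume` (or `voxel_size`) to locate the segment")
    vs <- if (!is.null(voxel_size)) voxel_size else volume$voxel_size
    d <- dim(volume$intensities)
    mask <- array(FALSE, d)
    mask[segment$voxel_idx] <- TRUE
  } else {
    mask <- segment
    if (is.null(voxel_size)) stop("`voxel_size` required with a mask")
    vs <- voxel_size
  }
  if (!any(mask)) stop("empty segment")
  measure_mask(mask, vs)
}

measure_mask <- function(mask, voxel_size) {
  V <- sum(mask) * prod(voxel_size)
  A <- mask_surface_area(mask, voxel_size)
  list(volume = V, surface_area = A, sphericity = sphericity(V, A))
}

#' Wadell sphericity
#'
#' `psi = pi^(1/3) (6 V)^(2/3) / A`: the ratio of the surface area of a
#' sphere of volume `V` to the actual surface area `A`.  Equals 1 for a
#' sphere and is smaller for any other shape; scale-invariant.
#'
#' @param V Volume (um^3), > 0.
#' @param A Surface area (um^2), > 0.
#' @return Dimensionless sphericity.
#' @examples
#' sphericity(1, (36 * pi)^(1/3))       # sphere of unit volume -> 1
#' s <- 2; sphericity(s^3, 6 * s^2)     # cube -> (pi/6)^(1/3) ~ 0.806
#' @export
sphericity <- function(V, A) {
  check_scalar(V, "V", positive = TRUE)
  check_scalar(A, "A", positive = TRUE)
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

# --- binary morphology and labelling helpers (6-neighbourhood) -----------

dilate6 <- function(m) {
  r <- m
  for (ax in 1:3) r <- r | shift3d(m, 1, ax) | shift3d(m, -1, ax)
  r
}
erode6 <- function(m) !dilate6(!m)

# 3D connected-component labelling (6-connectivity) via an adjacency graph.
label_components3d <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  lab <- array(0L, d)
  if (!length(idx)) return(lab)
  pos <- arrayInd(idx, d)
  key <- (pos[, 3] - 1L) * d[1] * d[2] + (pos[, 2] - 1L) * d[1] + pos[, 1]
  lut <- integer(prod(d)); lut[key] <- seq_along(idx)
  edges <- integer(0)
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- pos[ok, , drop = FALSE]
    nb[, ax] <- nb[, ax] + 1L
    nkey <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
    hit <- lut[nkey] > 0
    if (any(hit))
      edges <- c(edges, rbind(which(ok)[hit], lut[nkey[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  lab[idx] <- as.integer(comp)
  lab
}

# Surface area of a binary mask by marching tetrahedra on the box-smoothed
# indicator (iso-level 0.5).  Voxel sizes (z, y, x) um.
mask_surface_area <- function(mask, voxel_size) {
  d <- dim(mask)
  f <- array(0, d + 2L)
  f[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  f <- box_smooth3(f)
  d2 <- dim(f)
  n1 <- d2[1] - 1L; n2 <- d2[2] - 1L; n3 <- d2[3] - 1L
  # cube corner offsets, bit order (d1, d2, d3)
  off <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
               c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
  V <- matrix(0, n1 * n2 * n3, 8)
  for (v in 1:8)
    V[, v] <- as.vector(f[(1:n1) + off[v, 1], (1:n2) + off[v, 2],
                          (1:n3) + off[v, 3]])
  iso <- 0.5
  mixed <- rowSums(V > iso) %in% 1:7
  V <- V[mixed, , drop = FALSE]
  if (!nrow(V)) return(0)
  # physical corner coords: axis 1 = z etc.
  corn <- off * matrix(voxel_size, 8, 3, byrow = TRUE)
  tets <- rbind(c(1,6,2,8), c(1,2,4,8), c(1,4,3,8),
                c(1,3,7,8), c(1,7,5,8), c(1,5,6,8))
  tri_area <- function(p1, p2, p3) {
    u <- p2 - p1; w <- p3 - p1
    cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
    cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
    cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  interp <- function(ci, cj, vi, vj) {
    t <- (iso - vi) / (vj - vi)
    cbind(corn[ci, 1] + t * (corn[cj, 1] - corn[ci, 1]),
          corn[ci, 2] + t * (corn[cj, 2] - corn[ci, 2]),
          corn[ci, 3] + t * (corn[cj, 3] - corn[ci, 3]))
  }
  total <- 0
  for (t in 1:6) {
    vid <- tets[t, ]
    vals <- V[, vid, drop = FALSE]
    code <- (vals[, 1] > iso) + 2L * (vals[, 2] > iso) +
            4L * (vals[, 3] > iso) + 8L * (vals[, 4] > iso)
    for (cs in 1:14) {
      rows <- which(code == cs)
      if (!length(rows)) next
      b <- as.logical(bitwAnd(cs, c(1L, 2L, 4L, 8L)))
      inn <- which(b); out <- which(!b)
      if (length(inn) == 3) { tmp <- inn; inn <- out; out <- tmp }
      vv <- vals[rows, , drop = FALSE]
      if (length(inn) == 1L) {
        i <- inn[1]
        p1 <- interp(vid[i], vid[out[1]], vv[, i], vv[, out[1]])
        p2 <- interp(vid[i], vid[out[2]], vv[, i], vv[, out[2]])
        p3 <- interp(vid[i], vid[out[3]], vv[, i], vv[, out[3]])
        total <- total + sum(tri_area(p1, p2, p3))
      } else {
        i <- inn[1]; j <- inn[2]; k <- out[1]; l <- out[2]
        pik <- interp(vid[i], vid[k], vv[, i], vv[, k])
        pil <- interp(vid[i], vid[l], vv[, i], vv[, l])
        pjl <- interp(vid[j], vid[l], vv[, j], vv[, l])
        pjk <- interp(vid[j], vid[k], vv[, j], vv[, k])
        total <- total + sum(tri_area(pik, pil, pjl)) +
                 sum(tri_area(pik, pjl, pjk))
      }
    }
  }
  total
}
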