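#' Filament (TZP trace) objects
#'
#' A filament is an ordered, unbranched 3D polyline in micrometres with a
#' radius at every point.  By convention the first point is the cell-body
#' origin of the projection and the last point is its tip.
#'
#' @param points Numeric matrix with columns `(x, y, z)` in um; one row per
#'   point.  A single-point (degenerate, zero-length) filament is allowed.
#' @param radii Per-point radii (um); recycled if scalar.
#' @param parent_cell Optional label of the granulosa cell the filament
#'   belongs to.
#' @return An object of class `filament`.
#' @export
filament <- function(points, radii = 0.2, parent_cell = NA) {
  points <- as.matrix(points)
  if (ncol(points) == 2L) points <- cbind(points, 0)
  if (ncol(points) != 3L) stop("`points` must have columns (x, y, z)")
  if (nrow(points) < 1L) stop("a filament needs at least one point")
  radii <- rep_len(as.numeric(radii), nrow(points))
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be positive and finite")
  structure(list(points = unname(points), radii = radii,
                 parent_cell = parent_cell),
            class = "filament")
}

#' @export
print.filament <- function(x, ...) {
  cat(sprintf("filament: %d points, length %.3f um, mean radius %.3f um%s\n",
              nrow(x$points), filament_length(x), mean(x$radii),
              if (!is.na(x$parent_cell)) sprintf(", cell %s", x$parent_cell)
              else ""))
  invisible(x)
}

#' Read filaments from an SWC file
#'
#' Parses the SWC tracing dialect (one point per line:
#' `id type x y z radius parent`, `#` comments) and returns each rooted
#' unbranched path as one [filament()].  The root (parent = -1) is taken as
#' the cell-body origin and the leaf as the tip.  Branch points and cyclic
#' parent links are rejected: TZPs are modelled as unbranched processes.
#'
#' @param path SWC file path; coordinates and radii in um.
#' @return A list of `filament` objects (possibly empty).
#' @export
read_filaments_swc <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(list())
  fields <- do.call(rbind, lapply(strsplit(lines, "\\s+"), function(f) {
    if (length(f) != 7L) stop("malformed SWC line (need 7 fields)")
    as.numeric(f)
  }))
  colnames(fields) <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (anyDuplicated(fields[, "id"])) stop("duplicate SWC node ids")
  if (any(fields[, "radius"] <= 0)) stop("non-positive radius in SWC file")
  id <- fields[, "id"]; parent <- fields[, "parent"]
  child_count <- table(factor(parent[parent != -1], levels = id))
  if (any(child_count > 1)) stop("branch point in SWC file; TZPs are modelled unbranched")
  roots <- which(parent == -1)
  if (!length(roots)) stop("no root node (parent = -1) in SWC file")
  if (any(!(parent[parent != -1] %in% id)))
    stop("dangling parent reference in SWC file")
  visited <- integer(0)
  out <- lapply(roots, function(r) {
    ord <- r
    repeat {
      nxt <- which(parent == id[ord[length(ord)]])
      if (!length(nxt)) break
      if (nxt %in% ord) stop("cyclic parent links in SWC file")
      ord <- c(ord, nxt)
    }
    visited <<- c(visited, ord)
    filament(fields[ord, c("x", "y", "z"), drop = FALSE],
             fields[ord, "radius"])
  })
  if (length(visited) != nrow(fields))
    stop("cyclic parent links in SWC file (nodes unreachable from any root)")
  out
}

#' Write filaments to an SWC file
#'
#' @param filaments A list of [filament()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_filaments_swc <- function(filaments, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# SWC filament traces (um); id type x y z radius parent", con)
  nid <- 0L
  for (f in filaments) {
    np <- nrow(f$points)
    ids <- nid + seq_len(np)
    parents <- c(-1L, ids[-np])
    writeLines(sprintf("%d 0 %.9g %.9g %.9g %.9g %d", ids,
                       f$points[, 1], f$points[, 2], f$points[, 3],
                       f$radii, parents), con)
    nid <- nid + np
  }
  invisible(path)
}
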