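#' Calibrated image containers
#'
#' `goc_image()` wraps a 2D intensity matrix (rows = y, cols = x) with its
#' physical pixel size; `goc_volume()` wraps a 3D array in `(z, y, x)` axis
#' order with per-axis voxel sizes.  Physical coordinates are pixel/voxel
#' centres: the centre of 0-based index `i` along an axis with spacing `h`
#' lies at `i * h` micrometres.
#'
#' @param intensities Non-negative numeric matrix (2D) or array (3D).
#' @param pixel_size Pixel size in um (2D).
#' @param voxel_size `(z, y, x)` voxel sizes in um (3D).
#' @param channel Channel label.
#' @return An object of class `goc_image` or `goc_volume`.
#' @export
goc_image <- function(intensities, pixel_size, channel = "phalloidin") {
  if (!is.matrix(intensities)) stop("`intensities` must be a matrix")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  check_scalar(pixel_size, "pixel_size", positive = TRUE)
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 channel = as.character(channel)),
            class = "goc_image")
}

#' @rdname goc_image
#' @export
goc_volume <- function(intensities, voxel_size, channel = "gfp") {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array in (z, y, x) order")
  if (any(intensities < 0)) stop("intensities must be non-negative")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("`voxel_size` must be three positive (z, y, x) sizes")
  structure(list(intensities = intensities,
                 voxel_size = as.numeric(voxel_size),
                 channel = as.character(channel)),
            class = "goc_volume")
}

#' @export
print.goc_image <- function(x, ...) {
  cat(sprintf("goc_image: %d x %d pixels at %.3f um/px (%.1f x %.1f um), channel '%s'\n",
              nrow(x$intensities), ncol(x$intensities), x$pixel_size,
              nrow(x$intensities) * x$pixel_size,
              ncol(x$intensities) * x$pixel_size, x$channel))
  invisible(x)
}

#' @export
print.goc_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("goc_volume: %d x %d x %d voxels (z, y, x) at (%.2f, %.2f, %.2f) um, channel '%s'\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$channel))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Write a calibrated image or volume to TIFF
#'
#' Intensities are written as 16-bit TIFF (scaled to the data maximum; the
#' scale factor is stored so reads invert it exactly to double precision).
#' Calibration and channel labels are stored in a JSON sidecar
#' (`<path>.json`), since baseline TIFF tags do not round-trip physical
#' pixel sizes through the writer used here.  Multi-channel data may be
#' passed as a named list of images sharing one geometry.
#'
#' @param img A `goc_image`, `goc_volume`, or named list of either.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  imgs <- if (inherits(img, c("goc_image", "goc_volume"))) {
    stats::setNames(list(img), img$channel)
  } else img
  if (!length(imgs)) stop("nothing to write")
  is3d <- inherits(imgs[[1]], "goc_volume")
  planes <- list()
  scales <- numeric(length(imgs))
  for (ci in seq_along(imgs)) {
    a <- imgs[[ci]]$intensities
    mx <- max(a, 1e-12)
    scales[ci] <- mx
    a <- a / mx
    if (is3d) {
      for (z in seq_len(dim(a)[1])) planes <- c(planes, list(a[z, , ]))
    } else planes <- c(planes, list(a))
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(
    kind = if (is3d) "volume" else "plane",
    channels = names(imgs),
    scale = scales,
    n_planes_per_channel = if (is3d) dim(imgs[[1]]$intensities)[1] else 1L
  )
  if (is3d) meta$voxel_size_um <- imgs[[1]]$voxel_size
  else meta$pixel_size_um <- imgs[[1]]$pixel_size
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibrated image or volume from TIFF
#'
#' Calibration is taken from the JSON sidecar written by [write_image()]
#' when present, else from the `pixel_size`/`voxel_size` arguments.  A TIFF
#' with neither sidecar nor explicit calibration raises an error - physical
#' units are never silently defaulted.
#'
#' @param path TIFF path.
#' @param channel Channel label to extract (defaults to the first).
#' @param pixel_size,voxel_size Calibration overrides (um) used when no
#'   sidecar metadata exists.
#' @return A `goc_image` or `goc_volume`.
#' @export
read_image <- function(path, channel = NULL, pixel_size = NULL,
                       voxel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  planes <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(planes)) planes <- list(planes)
  sc <- sidecar_path(path)
  meta <- if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE)
          else NULL
  if (is.null(meta)) {
    # raw TIFF with no sidecar: single channel, calibration must be supplied
    if (is.null(pixel_size) && is.null(voxel_size))
      stop("TIFF carries no calibration metadata and no pixel_size/voxel_size was supplied")
    meta <- list(kind = if (length(planes) > 1 || !is.null(voxel_size))
                          "volume" else "plane",
                 channels = if (is.null(channel)) "unknown" else channel,
                 scale = rep(1, 1), n_planes_per_channel = length(planes))
  }
  chs <- meta$channels
  ci <- if (is.null(channel)) 1L else match(channel, chs)
  if (is.na(ci))
    stop(sprintf("channel '%s' absent; available: %s", channel,
                 paste(chs, collapse = ", ")))
  npc <- meta$n_planes_per_channel
  sel <- planes[((ci - 1L) * npc + 1L):(ci * npc)]
  sel <- lapply(sel, function(p) p * meta$scale[ci])
  if (identical(meta$kind, "volume")) {
    vs <- if (!is.null(meta$voxel_size_um)) meta$voxel_size_um else voxel_size
    if (is.null(vs)) stop("volume lacks voxel size calibration")
    arr <- array(0, c(length(sel), nrow(sel[[1]]), ncol(sel[[1]])))
    for (z in seq_along(sel)) arr[z, , ] <- sel[[z]]
    goc_volume(arr, vs, chs[ci])
  } else {
    ps <- if (!is.null(meta$pixel_size_um)) meta$pixel_size_um else pixel_size
    if (is.null(ps)) stop("image lacks pixel size calibration")
    goc_image(sel[[1]], ps, chs[ci])
  }
}

#' Write and read homogeneous results tables
#'
#' CSV with stable column order and full-precision numerics (15 significant
#' digits), so a read-back compares equal to the written values.
#'
#' @param records A data.frame, or list of identically named lists/rows.
#' @param path Output CSV path.
#' @return `write_results_table()`: `path`, invisibly;
#'   `read_results_table()`: a data.frame.
#' @export
write_results_table <- function(records, path) {
  if (!is.data.frame(records)) {
    if (!length(records)) stop("no records to write")
    nms <- lapply(records, names)
    if (!all(vapply(nms, identical, logical(1), nms[[1]])))
      stop("records have heterogeneous schemas")
    records <- do.call(rbind, lapply(records, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  num <- vapply(records, function(x) is.double(x), logical(1))
  out <- records
  out[num] <- lapply(records[num], function(x) {
    s <- sprintf("%.17g", x)  # shortest-exact is not available; 17 sig digits round-trips doubles
    s[is.na(x)] <- NA
    s
  })
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}
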