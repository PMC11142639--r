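#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive per-specimen seeds (< 2^31) deterministically from a master seed.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite numeric scalar")
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (nonneg && x < 0) stop_field(field, "must be >= 0")
  invisible(x)
}

# Bilinear interpolation on a matrix at continuous 1-based (row, col)
# positions.  Positions must lie within [1, nrow] x [1, ncol].
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  if (any(row < 1 | row > nr | col < 1 | col > nc))
    stop("sampling positions fall outside the image", call. = FALSE)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Shift a 3D array by k voxels along axis `ax`, zero-filling.
shift3d <- function(a, k, ax) {
  d <- dim(a)
  if (k == 0) return(a)
  out <- array(0, d)
  src <- dst <- lapply(d, seq_len)
  if (k > 0) { dst[[ax]] <- (1 + k):d[ax]; src[[ax]] <- 1:(d[ax] - k) }
  else       { dst[[ax]] <- 1:(d[ax] + k); src[[ax]] <- (1 - k):d[ax] }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# 3^3 box-mean mollifier for 3D arrays (used before iso-surfacing).
box_smooth3 <- function(a) {
  s <- array(0, dim(a))
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1)
    s <- s + shift3d(shift3d(shift3d(a, dx, 3), dy, 2), dz, 1)
  s / 27
}
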