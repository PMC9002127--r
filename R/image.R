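# Small image utilities shared by the phantom generator and the augmenter.
# Images are numeric matrices in [0, 255], row = y (top-down), col = x.

#' Read / write 8-bit grayscale PNG images
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param path File path.
#' @return `read_image()`: numeric matrix in `[0, 255]`.
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- x[, , 1]
  x * 255
}

#' Sample an image under an inverse affine map (bilinear)
#'
#' For every destination pixel `(x, y)` (0-based), the source location is
#' `A %*% c(x, y) + t`; the image is sampled bilinearly, with out-of-bounds
#' locations filled with `fill`. This one function backs rotation, scaling
#' and crop-resize so the annotation transforms in the augmenter provably use
#' the same convention as the pixels.
#'
#' @param image Numeric matrix.
#' @param A 2x2 matrix of the inverse (dst -> src) linear part.
#' @param t Length-2 translation of the inverse map.
#' @param out_shape `(H, W)` of the output (default: input shape).
#' @param fill Fill value for out-of-bounds samples (default 0).
#' @return Numeric matrix `out_shape`.
#' @export
warp_affine <- function(image, A, t, out_shape = dim(image), fill = 0) {
  H <- nrow(image); W <- ncol(image)
  ho <- out_shape[1]; wo <- out_shape[2]
  dx <- rep(0:(wo - 1), each = ho)
  dy <- rep(0:(ho - 1), times = wo)
  sx <- A[1, 1] * dx + A[1, 2] * dy + t[1]
  sy <- A[2, 1] * dx + A[2, 2] * dy + t[2]
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  # clamp the four neighbours; track validity for fill
  valid <- sx >= -0.5 & sx <= W - 0.5 & sy >= -0.5 & sy <= H - 0.5
  cx0 <- pmin(pmax(x0, 0), W - 1); cx1 <- pmin(pmax(x0 + 1, 0), W - 1)
  cy0 <- pmin(pmax(y0, 0), H - 1); cy1 <- pmin(pmax(y0 + 1, 0), H - 1)
  idx <- function(xx, yy) yy + 1 + H * xx
  v <- (1 - fy) * ((1 - fx) * image[idx(cx0, cy0)] + fx * image[idx(cx1, cy0)]) +
    fy * ((1 - fx) * image[idx(cx0, cy1)] + fx * image[idx(cx1, cy1)])
  v[!valid] <- fill
  matrix(v, ho, wo)
}

# Smooth low-frequency random field in [0,1], used for background texture.
smooth_field <- function(ny, nx, n_waves = 4) {
  f <- matrix(0, ny, nx)
  gx <- matrix(rep(0:(nx - 1), each = ny), ny, nx) / nx
  gy <- matrix(rep(0:(ny - 1), times = nx), ny, nx) / ny
  for (i in seq_len(n_waves)) {
    kx <- stats::runif(1, 0.5, 3); ky <- stats::runif(1, 0.5, 3)
    ph <- stats::runif(2, 0, 2 * pi)
    amp <- stats::runif(1, 0.3, 1)
    f <- f + amp * cos(2 * pi * (kx * gx) + ph[1]) * cos(2 * pi * (ky * gy) + ph[2])
  }
  (f - min(f)) / max(1e-9, diff(range(f)))
}

# Evaluate code under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
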