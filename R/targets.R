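#' Per-image annotation
#'
#' @param image_id Identifier (file stem).
#' @param ellipse An [ellipse()] for positive images, `NULL` for negatives.
#' @param pixel_size_mm Physical pixel size, mm per pixel (> 0).
#' @param is_negative Logical; negative images carry no ellipse.
#' @return Object of class `"annotation"`.
#' @export
annotation <- function(image_id, ellipse = NULL, pixel_size_mm,
                       is_negative = is.null(ellipse)) {
  stopifnot(pixel_size_mm > 0)
  if (is_negative && !is.null(ellipse))
    stop("annotation: negative images carry no ellipse")
  if (!is_negative && is.null(ellipse))
    stop("annotation: positive images require an ellipse")
  structure(list(image_id = as.character(image_id), ellipse = ellipse,
                 pixel_size_mm = pixel_size_mm, is_negative = is_negative),
            class = "annotation")
}

#' Read / write the annotation CSV dialect
#'
#' One row per image, UTF-8, '.' decimal, documented header:
#' `image_id,cx,cy,a,b,theta_deg,pixel_size_mm,is_negative`. `a` and `b` are
#' SEMI-axes in pixels; `theta_deg` is the short-axis-from-vertical angle in
#' `[0, 180)`. Negative rows carry `NA` ellipse fields.
#'
#' @param path CSV file path.
#' @return `read_annotations()`: a list of [annotation()] objects.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "cx", "cy", "a", "b", "theta_deg",
            "pixel_size_mm", "is_negative")
  if (!all(need %in% names(df)))
    stop("read_annotations: missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    neg <- as.logical(r$is_negative)
    e <- if (neg) NULL else ellipse(r$cx, r$cy, r$a, r$b, r$theta_deg)
    annotation(r$image_id, e, r$pixel_size_mm, neg)
  })
}

#' @param anns List of [annotation()] objects.
#' @rdname read_annotations
#' @export
write_annotations <- function(anns, path) {
  rows <- lapply(anns, function(an) {
    e <- an$ellipse
    data.frame(image_id = an$image_id,
               cx = if (is.null(e)) NA_real_ else e$cx,
               cy = if (is.null(e)) NA_real_ else e$cy,
               a = if (is.null(e)) NA_real_ else e$a,
               b = if (is.null(e)) NA_real_ else e$b,
               theta_deg = if (is.null(e)) NA_real_ else e$theta,
               pixel_size_mm = an$pixel_size_mm,
               is_negative = an$is_negative)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Splat an enclosing box onto the heatmap grid as a 2-D Gaussian
#'
#' The box center maps to grid coordinates `(bx/s, by/s)`; the kernel is the
#' axis-aligned Gaussian `exp(-((px - bx/s)^2 / (2 sa^2) +
#' (py - by/s)^2 / (2 sb^2)))` with box-size-adaptive standard deviations
#' `sa = w / (6 s)`, `sb = h / (6 s)` so the +-3 sigma extent matches the box.
#' The integer center cell is clamped to exactly 1; overlapping objects
#' combine by elementwise max.
#'
#' @param box An `"aabox"`.
#' @param stride Output stride `s` (default 4).
#' @param grid_shape `(ny, nx)` heatmap dimensions.
#' @param heatmap Optional existing grid to splat into (for multiple objects).
#' @return Matrix `ny x nx` with values in `[0, 1]`, row = y, col = x.
#' @export
splat_gaussian <- function(box, stride, grid_shape, heatmap = NULL) {
  ny <- grid_shape[1]; nx <- grid_shape[2]
  if (is.null(heatmap)) heatmap <- matrix(0, ny, nx)
  gx <- box$bx / stride
  gy <- box$by / stride
  ix <- floor(gx); iy <- floor(gy)
  if (ix < 0 || ix >= nx || iy < 0 || iy >= ny) {
    warning("splat_gaussian: box center outside the grid; empty heatmap")
    return(heatmap)
  }
  sa <- max(box$w / (6 * stride), 1e-3)
  sb <- max(box$h / (6 * stride), 1e-3)
  px <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  py <- matrix(rep(0:(ny - 1), times = nx), ny, nx)
  g <- exp(-((px - gx)^2 / (2 * sa^2) + (py - gy)^2 / (2 * sb^2)))
  g[iy + 1, ix + 1] <- 1
  pmax(heatmap, g)
}

#' Sub-pixel center offset
#'
#' The stride-s grid stores the center at an integer cell; the fractional
#' remainder `(cx/s - floor(cx/s), cy/s - floor(cy/s))` compensates the
#' discretization error and makes center reconstruction exact.
#'
#' @param cx,cy Center, pixels.
#' @param stride Output stride.
#' @return Numeric `(ox, oy)`, each in `[0, 1)`.
#' @export
encode_offset <- function(cx, cy, stride) {
  c(ox = cx / stride - floor(cx / stride),
    oy = cy / stride - floor(cy / stride))
}

#' Encode an annotation into stride-4 training targets
#'
#' Assembles the full target set for one image: Gaussian heatmap from the
#' ellipse's enclosing box, sub-pixel offset, semi-axes (in input-image
#' pixels), angle, and the GT Gaussian embedding used by the KLD loss.
#' Negative images yield an all-zero heatmap and no regression targets.
#'
#' @param ann An [annotation()].
#' @param stride Output stride (default 4).
#' @param image_shape `(H, W)` of the input image, pixels.
#' @return Object of class `"target_set"`: `heatmap` (ny x nx), `offset`,
#'   `axes` (semi-axes, pixels), `angle` (deg), `center_index` (0-based
#'   `(ix, iy)`), `gt_gaussian`, `n_objects`.
#' @export
encode_targets <- function(ann, stride = 4L, image_shape) {
  H <- image_shape[1]; W <- image_shape[2]
  ny <- H %/% stride; nx <- W %/% stride
  if (ann$is_negative) {
    return(structure(list(heatmap = matrix(0, ny, nx), offset = NULL,
                          axes = NULL, angle = NULL, center_index = NULL,
                          gt_gaussian = NULL, n_objects = 0L,
                          stride = stride),
                     class = "target_set"))
  }
  e <- ann$ellipse
  if (e$cx < 0 || e$cx >= W || e$cy < 0 || e$cy >= H)
    stop("encode_targets: ellipse center outside the image")
  box <- enclosing_box(e)
  structure(list(
    heatmap = splat_gaussian(box, stride, c(ny, nx)),
    offset = encode_offset(e$cx, e$cy, stride),
    axes = c(a = e$a, b = e$b),
    angle = e$theta,
    center_index = c(ix = floor(e$cx / stride), iy = floor(e$cy / stride)),
    gt_gaussian = ellipse_to_gaussian(e),
    n_objects = 1L,
    stride = stride
  ), class = "target_set")
}

#' Manufacture oracle head maps from a target set
#'
#' Builds a `detection_output` whose maps hold the encoded targets exactly
#' (heatmap as-is; offset/axes/angle written at the center cell, SSR
#' probabilities one-hot from the reference encoder). Decoding these maps must
#' reproduce the annotation: the codec identity used throughout the tests and
#' as a model-free oracle.
#'
#' @param ts A `"target_set"`.
#' @param ssr An [ssr_config()].
#' @return A `"detection_output"` (see [decode_detections()]).
#' @export
targets_to_detection_output <- function(ts, ssr = ssr_config()) {
  ny <- nrow(ts$heatmap); nx <- ncol(ts$heatmap)
  K <- length(ssr$stages)
  nprob <- sum(ssr$stages)
  out <- list(heatmap = array(ts$heatmap, c(ny, nx)),
              offset = array(0, c(ny, nx, 2)),
              axes = array(1e-3, c(ny, nx, 2)),
              ssr_probs = array(0, c(ny, nx, nprob)),
              ssr_eta = array(0, c(ny, nx, nprob)),
              ssr_delta = rep(0, K),
              stride = ts$stride)
  # uniform per-stage probabilities everywhere so the normalization contract
  # holds even off-center
  ofs <- 0L
  for (k in seq_len(K)) {
    out$ssr_probs[, , (ofs + 1):(ofs + ssr$stages[k])] <- 1 / ssr$stages[k]
    ofs <- ofs + ssr$stages[k]
  }
  if (ts$n_objects > 0) {
    ix <- ts$center_index["ix"] + 1L; iy <- ts$center_index["iy"] + 1L
    out$offset[iy, ix, ] <- ts$offset
    out$axes[iy, ix, ] <- ts$axes
    enc <- ssr_encode_reference(ts$angle, ssr)
    ofs <- 0L
    for (k in seq_len(K)) {
      out$ssr_probs[iy, ix, (ofs + 1):(ofs + ssr$stages[k])] <- enc$probs[[k]]
      ofs <- ofs + ssr$stages[k]
    }
  }
  structure(out, class = "detection_output")
}
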