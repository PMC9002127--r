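#' Extract heatmap peaks
#'
#' A cell is a peak if it is the maximum of its 3x3 neighbourhood and its
#' score reaches the threshold. Peaks are returned sorted by score and
#' truncated to `max_peaks` (default 1: a standard plane contains one head).
#' An empty result is a valid output for a negative image.
#'
#' @param heatmap Matrix in `[0, 1]` (row = y, col = x).
#' @param max_peaks Maximum number of peaks (default 1).
#' @param threshold Minimum score (default 0.3).
#' @return Data frame with 0-based grid columns `ix`, `iy` and `score`.
#' @export
extract_peaks <- function(heatmap, max_peaks = 1L, threshold = 0.3) {
  ny <- nrow(heatmap); nx <- ncol(heatmap)
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- heatmap
  is_max <- heatmap >= threshold
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[2:(ny + 1) + dy, 2:(nx + 1) + dx]
    is_max <- is_max & (heatmap >= nb)
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(data.frame(ix = integer(0), iy = integer(0), score = numeric(0)))
  sc <- heatmap[idx]
  ord <- order(sc, decreasing = TRUE)
  keep <- ord[seq_len(min(max_peaks, length(ord)))]
  data.frame(ix = idx[keep, 2] - 1L, iy = idx[keep, 1] - 1L,
             score = sc[keep])
}

# Assemble the SSR prediction at one grid cell from the head maps.
ssr_prediction_at <- function(out, iy1, ix1, ssr) {
  K <- length(ssr$stages)
  probs <- vector("list", K); eta <- vector("list", K)
  ofs <- 0L
  for (k in seq_len(K)) {
    rng <- ofs + seq_len(ssr$stages[k])
    probs[[k]] <- as.numeric(out$ssr_probs[iy1, ix1, rng])
    eta[[k]] <- as.numeric(out$ssr_eta[iy1, ix1, rng])
    ofs <- ofs + ssr$stages[k]
  }
  list(probs = probs, delta = as.numeric(out$ssr_delta), eta = eta)
}

#' Decode head maps into scored oriented ellipses
#'
#' For each heatmap peak `(ix, iy)` the center is reconstructed as
#' `((ix + ox) s, (iy + oy) s)`, the semi-axes are read off the axes map at
#' the cell (sorted so `a >= b`), and the angle is decoded from the cell's
#' SSR probabilities and shifts together with the image-level `Delta`.
#'
#' @param out A `"detection_output"` (see [detection_output()] and
#'   [targets_to_detection_output()]).
#' @param ssr An [ssr_config()].
#' @param threshold Peak score threshold (default 0.3).
#' @param max_peaks Maximum detections (default 1).
#' @return List of scored detections, each
#'   `list(ellipse = <ellipse>, score = <numeric>)`.
#' @export
decode_detections <- function(out, ssr = ssr_config(), threshold = 0.3,
                              max_peaks = 1L) {
  s <- out$stride
  peaks <- extract_peaks(out$heatmap, max_peaks, threshold)
  dets <- list()
  for (r in seq_len(nrow(peaks))) {
    ix <- peaks$ix[r]; iy <- peaks$iy[r]
    iy1 <- iy + 1L; ix1 <- ix + 1L
    ox <- out$offset[iy1, ix1, 1]; oy <- out$offset[iy1, ix1, 2]
    cx <- (ix + ox) * s; cy <- (iy + oy) * s
    ax <- out$axes[iy1, ix1, 1]; bx <- out$axes[iy1, ix1, 2]
    a <- max(ax, bx); b <- min(ax, bx)
    theta <- ssr_decode(ssr_prediction_at(out, iy1, ix1, ssr), ssr)
    if (!all(is.finite(c(cx, cy, a, b, theta))) || a <= 0) {
      warning("decode_detections: dropping non-finite detection")
      next
    }
    dets[[length(dets) + 1]] <-
      list(ellipse = ellipse(cx, cy, a, b, theta), score = peaks$score[r])
  }
  dets
}

#' Predict head circumference on one image
#'
#' Runs the model, decodes the single best detection and converts its
#' semi-axes to mm through the pixel size; no segmentation, contour
#' extraction or ellipse-fitting stage exists anywhere in the path. When no
#' peak reaches the threshold the result is an explicit "no head detected"
#' value, not an error.
#'
#' @param image Matrix in `[0, 255]` (as from [read_image()]) or `[0, 1]`.
#' @param model A trained `"fh_model"`.
#' @param pixel_size_mm Pixel size, mm.
#' @param threshold Score threshold (default 0.3).
#' @return List with `detected` (logical), and when detected: `ellipse`,
#'   `score`, `hc_mm`.
#' @export
predict_hc <- function(image, model, pixel_size_mm, threshold = 0.3) {
  if (max(image) > 1.5) image <- image / 255
  fwd <- nn_forward(model, image, train = FALSE, want_cache = FALSE)
  dets <- decode_detections(detection_output(fwd$out, 1L),
                            model$cfg$ssr, threshold, max_peaks = 1L)
  if (length(dets) == 0)
    return(list(detected = FALSE, ellipse = NULL, score = NA_real_,
                hc_mm = NA_real_))
  d <- dets[[1]]
  list(detected = TRUE, ellipse = d$ellipse, score = d$score,
       hc_mm = head_circumference(d$ellipse$a * pixel_size_mm,
                                  d$ellipse$b * pixel_size_mm))
}
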