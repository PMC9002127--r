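#' The discrete augmentation grids
#'
#' Rotation `[-30, 30]` degrees in steps of 10, scaling `[0.85, 1.15]` in
#' steps of 0.05, gamma `[0.5, 1.5]` in steps of 0.1, and horizontal flip.
#'
#' @return Named list of parameter vectors.
#' @export
augmentation_grid <- function() {
  list(rotate = seq(-30, 30, by = 10),
       scale = seq(0.85, 1.15, by = 0.05),
       gamma = seq(0.5, 1.5, by = 0.1),
       flip = c(FALSE, TRUE))
}

#' Apply one augmentation to a phantom sample
#'
#' The image and its annotation transform together:
#' * `rotate` by `phi` degrees about the image center: the ellipse center is
#'   rotated and `theta' = (theta - phi) mod 180`;
#' * `scale` by `sigma` about the center: center and semi-axes scale by
#'   `sigma` and the pixel size divides by `sigma`, so HC in mm is invariant;
#' * `gamma` remaps intensities `(I/255)^gamma * 255`, annotation unchanged;
#' * `flip` mirrors horizontally: `cx' = W - 1 - cx`,
#'   `theta' = (180 - theta) mod 180`.
#'
#' @param sample A `"phantom_sample"`.
#' @param op One of `"rotate"`, `"scale"`, `"gamma"`, `"flip"`.
#' @param value Parameter value (angle, ratio, gamma factor, or logical).
#' @param on_exit What to do if the transformed ellipse leaves the frame:
#'   `"reject"` (error) or `"allow"`.
#' @return The augmented `"phantom_sample"`.
#' @export
augment <- function(sample, op = c("rotate", "scale", "gamma", "flip"),
                    value, on_exit = c("reject", "allow")) {
  op <- match.arg(op)
  on_exit <- match.arg(on_exit)
  img <- sample$image
  ann <- sample$annotation
  H <- nrow(img); W <- ncol(img)
  ctr <- c((W - 1) / 2, (H - 1) / 2)
  fill <- stats::median(img[c(1:H, (W - 1) * H + 1:H)]) # border estimate
  e <- ann$ellipse
  new_ps <- ann$pixel_size_mm

  if (op == "rotate") {
    phi <- value * pi / 180
    # forward point map p' = R(-phi) (p - ctr) + ctr in (x, y-down) coords,
    # so the stored orientation decreases by phi; the image is resampled
    # through the inverse map.
    Rinv <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    img2 <- warp_affine(img, Rinv, ctr - Rinv %*% ctr, fill = fill)
    if (!is.null(e)) {
      Rf <- t(Rinv)
      p <- Rf %*% (c(e$cx, e$cy) - ctr) + ctr
      e <- ellipse(p[1], p[2], e$a, e$b, (e$theta - value) %% 180)
    }
  } else if (op == "scale") {
    s <- value
    Ainv <- diag(c(1 / s, 1 / s))
    img2 <- warp_affine(img, Ainv, ctr - ctr / s, fill = fill)
    if (!is.null(e)) {
      p <- (c(e$cx, e$cy) - ctr) * s + ctr
      e <- ellipse(p[1], p[2], e$a * s, e$b * s, e$theta)
    }
    new_ps <- ann$pixel_size_mm / s
  } else if (op == "gamma") {
    img2 <- round(255 * (pmin(pmax(img, 0), 255) / 255)^value)
  } else { # flip
    if (isTRUE(value)) {
      img2 <- img[, W:1, drop = FALSE]
      if (!is.null(e))
        e <- ellipse(W - 1 - e$cx, e$cy, e$a, e$b, (180 - e$theta) %% 180)
    } else img2 <- img
  }

  if (!is.null(e) && (e$cx < 0 || e$cx > W - 1 || e$cy < 0 || e$cy > H - 1)) {
    if (on_exit == "reject")
      stop("augment: transformed ellipse center left the frame")
  }
  structure(list(image = round(pmin(pmax(img2, 0), 255)),
                 annotation = annotation(
                   sprintf("%s_%s_%s", ann$image_id, op, format(value)),
                   e, new_ps, ann$is_negative),
                 seed = sample$seed),
            class = "phantom_sample")
}

#' Expand a sample list through the augmentation grid
#'
#' `mode = "single"` applies every value of every listed grid separately
#' (output count = sum of grid lengths per image); `mode = "compose"` applies
#' the full cartesian product (count = product of grid lengths). The
#' expansion factor is logged.
#'
#' @param samples List of `"phantom_sample"` objects.
#' @param grid Named list as from [augmentation_grid()]; subset to select.
#' @param mode `"single"` or `"compose"`.
#' @param quiet Suppress the expansion log line.
#' @return The expanded list of samples.
#' @export
expand_training_set <- function(samples, grid = augmentation_grid(),
                                mode = c("single", "compose"), quiet = FALSE) {
  mode <- match.arg(mode)
  if (length(grid) == 0) return(samples)
  out <- list()
  if (mode == "single") {
    for (s in samples)
      for (op in names(grid))
        for (v in grid[[op]])
          out[[length(out) + 1]] <- augment(s, op, v, on_exit = "allow")
    factor <- sum(lengths(grid))
  } else {
    combos <- expand.grid(grid, stringsAsFactors = FALSE)
    for (s in samples)
      for (i in seq_len(nrow(combos))) {
        a <- s
        for (op in names(grid)) a <- augment(a, op, combos[i, op],
                                             on_exit = "allow")
        out[[length(out) + 1]] <- a
      }
    factor <- nrow(combos)
  }
  if (!quiet)
    message("expand_training_set: ", length(samples), " -> ", length(out),
            " samples (factor ", factor, ", mode ", mode, ")")
  out
}
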