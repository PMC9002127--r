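#' Configuration of the synthetic skull-phantom generator
#'
#' The generator emulates what the detector actually faces in 2-D fetal
#' ultrasound standard planes: a bright, roughly elliptical skull ring of
#' variable size, eccentricity and orientation, with multiplicative speckle,
#' a smooth uneven background, and partial boundary dropout mimicking
#' acoustic shadowing at the skull poles. It makes no claim to physical
#' realism (no point-spread function, no attenuation).
#'
#' @param image_size `(H, W)` in pixels; default 96 x 96.
#' @param semi_axis_range Range of the semi-major axis `a`, pixels; by
#'   default 15-33 percent of the smaller image dimension.
#' @param eccentricity_range Range of `b / a` (default `[0.6, 1]`, typical of
#'   fetal skull outlines).
#' @param ring_thickness Full thickness of the skull ring, pixels.
#' @param ring_intensity `(mean, jitter)` of the ring brightness, 8-bit units.
#' @param speckle Standard deviation of the unit-mean multiplicative gamma
#'   speckle (0 disables it).
#' @param gap_fraction Fraction of the ring perimeter erased, in `[0, 0.5]`,
#'   split into two arcs at opposite poles.
#' @param background_texture Amplitude of the smooth background field, 8-bit
#'   units.
#' @param base_intensity Background base level, 8-bit units.
#' @param pixel_size_range Physical pixel size range, mm/px (HC18 spans
#'   0.052-0.6 mm).
#' @return Object of class `"phantom_config"`.
#' @export
phantom_config <- function(image_size = c(96L, 96L),
                           semi_axis_range = round(c(0.15, 0.33) *
                                                     min(image_size)),
                           eccentricity_range = c(0.6, 1),
                           ring_thickness = 3,
                           ring_intensity = c(170, 30),
                           speckle = 0.3,
                           gap_fraction = 0.2,
                           background_texture = 25,
                           base_intensity = 40,
                           pixel_size_range = c(0.052, 0.6)) {
  stopifnot(length(image_size) == 2, all(image_size >= 32),
            semi_axis_range[1] > 0, semi_axis_range[1] <= semi_axis_range[2],
            eccentricity_range[1] > 0, eccentricity_range[2] <= 1,
            ring_thickness > 0, gap_fraction >= 0, gap_fraction <= 0.5,
            pixel_size_range[1] > 0)
  margin <- ring_thickness + 2
  if (semi_axis_range[1] + margin >= min(image_size) / 2)
    stop("phantom_config: no ellipse in semi_axis_range fits the image ",
         "with the required margin")
  structure(list(image_size = as.integer(image_size),
                 semi_axis_range = semi_axis_range,
                 eccentricity_range = eccentricity_range,
                 ring_thickness = ring_thickness,
                 ring_intensity = ring_intensity,
                 speckle = speckle,
                 gap_fraction = gap_fraction,
                 background_texture = background_texture,
                 base_intensity = base_intensity,
                 pixel_size_range = pixel_size_range),
            class = "phantom_config")
}

# Signed approximate normal distance of every pixel to the ellipse contour,
# plus the parametric angle of the nearest contour point (for arc erasure).
ellipse_distance_field <- function(e, H, W) {
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), times = W), H, W)
  rr <- theta_to_psi(e$theta) * pi / 180
  u <- (x - e$cx) * cos(rr) + (y - e$cy) * sin(rr)
  v <- -(x - e$cx) * sin(rr) + (y - e$cy) * cos(rr)
  r <- sqrt((u / e$a)^2 + (v / e$b)^2)
  gnorm <- sqrt((u / e$a^2)^2 + (v / e$b^2)^2)
  d <- (r - 1) * r / pmax(gnorm, 1e-9)
  phi <- atan2(v / e$b, u / e$a) %% (2 * pi)
  list(d = d, phi = phi)
}

# Cumulative arc length of the ellipse over the parametric angle.
arc_length_table <- function(a, b, n = 1440) {
  phi <- seq(0, 2 * pi, length.out = n + 1)
  dens <- sqrt(a^2 * sin(phi)^2 + b^2 * cos(phi)^2)
  s <- c(0, cumsum((dens[-1] + dens[-(n + 1)]) / 2 * diff(phi)))
  list(phi = phi, s = s, total = s[n + 1])
}

# TRUE for parametric angles falling inside the erased arcs: two contiguous
# arcs of gap_fraction/2 of the *perimeter* each, half a perimeter apart.
in_gap <- function(phi, a, b, gap_fraction, start_frac) {
  if (gap_fraction <= 0) return(rep(FALSE, length(phi)))
  tab <- arc_length_table(a, b)
  s <- stats::approx(tab$phi, tab$s, xout = phi, rule = 2)$y / tab$total
  half <- gap_fraction / 2
  f1 <- (s - start_frac) %% 1
  f2 <- (s - (start_frac + 0.5)) %% 1
  (f1 < half) | (f2 < half)
}

#' Generate one synthetic skull phantom
#'
#' Deterministic given `(cfg, seed)`: the same pair always yields the same
#' image bytes and annotation.
#'
#' @param cfg A [phantom_config()].
#' @param seed Integer RNG seed for this sample.
#' @param image_id Identifier (default derived from the seed).
#' @return Object of class `"phantom_sample"`: `image` (8-bit matrix),
#'   `annotation` (with the exact generating ellipse and a pixel size drawn
#'   from `pixel_size_range`), `seed`.
#' @export
generate_phantom <- function(cfg = phantom_config(), seed = 1L,
                             image_id = sprintf("phantom_%06d", seed)) {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(seed, {
    H <- cfg$image_size[1]; W <- cfg$image_size[2]
    a <- stats::runif(1, cfg$semi_axis_range[1], cfg$semi_axis_range[2])
    b <- a * stats::runif(1, cfg$eccentricity_range[1], cfg$eccentricity_range[2])
    theta <- stats::runif(1, 0, 180)
    margin <- cfg$ring_thickness + 2
    # half-extents of the enclosing box bound the valid center range
    probe <- enclosing_box(ellipse(0, 0, a, b, theta))
    hx <- probe$w / 2 + margin; hy <- probe$h / 2 + margin
    if (hx >= W / 2 || hy >= H / 2)
      stop("generate_phantom: configured ellipse cannot fit the image")
    cx <- stats::runif(1, hx, W - 1 - hx)
    cy <- stats::runif(1, hy, H - 1 - hy)
    e <- ellipse(cx, cy, a, b, theta)

    df <- ellipse_distance_field(e, H, W)
    # anti-aliased ring profile: full intensity inside, linear 1 px falloff
    prof <- pmin(pmax(cfg$ring_thickness / 2 + 0.5 - abs(df$d), 0), 1)
    if (cfg$gap_fraction > 0) {
      gap_start <- stats::runif(1)
      gap <- in_gap(df$phi, a, b, cfg$gap_fraction, gap_start)
      prof[gap & abs(df$d) < cfg$ring_thickness] <- 0
    }
    ring_level <- cfg$ring_intensity[1] +
      stats::runif(1, -cfg$ring_intensity[2], cfg$ring_intensity[2])
    img <- cfg$base_intensity +
      cfg$background_texture * smooth_field(H, W) +
      ring_level * prof
    if (cfg$speckle > 0) {
      k <- 1 / cfg$speckle^2
      img <- img * matrix(stats::rgamma(H * W, shape = k, rate = k), H, W)
    }
    img <- round(pmin(pmax(img, 0), 255))
    ps <- stats::runif(1, cfg$pixel_size_range[1], cfg$pixel_size_range[2])
    structure(list(image = img,
                   annotation = annotation(image_id, e, ps),
                   seed = seed),
              class = "phantom_sample")
  })
}

#' Turn a positive phantom into a negative sample
#'
#' Two constructions: `"remove_fill"` erases the skull ring and fills it with
#' the surrounding background statistics; `"random_crop"` cuts a patch whose
#' axis-aligned IOU with the ground-truth enclosing box is below 0.3 and
#' resizes it to the input size. Either way the result carries
#' `is_negative = TRUE` and no ellipse.
#'
#' @param sample A positive `"phantom_sample"`.
#' @param mode `"remove_fill"` or `"random_crop"`.
#' @param seed Integer RNG seed.
#' @param max_iou Acceptance bound for the crop overlap (default 0.3).
#' @return A negative `"phantom_sample"`.
#' @export
make_negative <- function(sample, mode = c("remove_fill", "random_crop"),
                          seed = 1L, max_iou = 0.3) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "phantom_sample"), !sample$annotation$is_negative)
  e <- sample$annotation$ellipse
  img <- sample$image
  H <- nrow(img); W <- ncol(img)
  with_seed(seed, {
    if (mode == "remove_fill") {
      df <- ellipse_distance_field(e, H, W)
      t2 <- 2.5 # dilate past the anti-aliased edge
      band <- abs(df$d) <= t2 + 2
      ann_ring <- abs(df$d) > t2 + 2 & abs(df$d) <= t2 + 8
      m <- mean(img[ann_ring]); s <- stats::sd(img[ann_ring])
      fill <- stats::rnorm(sum(band), m, s)
      out <- img
      out[band] <- fill
      # light 3x3 box smoothing of the filled region so it blends in
      pad <- rbind(out[1, ], out, out[H, ])
      pad <- cbind(pad[, 1], pad, pad[, W])
      sm <- (pad[1:H, 1:W] + pad[1:H, 2:(W + 1)] + pad[1:H, 3:(W + 2)] +
               pad[2:(H + 1), 1:W] + pad[2:(H + 1), 2:(W + 1)] +
               pad[2:(H + 1), 3:(W + 2)] + pad[3:(H + 2), 1:W] +
               pad[3:(H + 2), 2:(W + 1)] + pad[3:(H + 2), 3:(W + 2)]) / 9
      out[band] <- sm[band]
      out <- round(pmin(pmax(out, 0), 255))
    } else {
      gt_box <- enclosing_box(e)
      ok <- FALSE
      for (i in seq_len(100)) {
        f <- stats::runif(1, 0.35, 0.65)
        ch <- round(f * H); cw <- round(f * W)
        y0 <- sample.int(H - ch + 1, 1) - 1
        x0 <- sample.int(W - cw + 1, 1) - 1
        crop_box <- structure(list(bx = x0 + (cw - 1) / 2, by = y0 + (ch - 1) / 2,
                                   w = cw, h = ch), class = "aabox")
        if (box_iou(crop_box, gt_box) < max_iou) { ok <- TRUE; break }
      }
      if (!ok)
        stop("make_negative: no crop with IOU < ", max_iou,
             " found in 100 attempts (image ", sample$annotation$image_id, ")")
      A <- diag(c(cw / W, ch / H))
      out <- warp_affine(img, A, c(x0, y0), out_shape = c(H, W),
                         fill = stats::median(img))
      out <- round(pmin(pmax(out, 0), 255))
    }
    structure(list(image = out,
                   annotation = annotation(
                     paste0(sample$annotation$image_id, "_neg_", mode),
                     NULL, sample$annotation$pixel_size_mm),
                   seed = seed),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_pos` positive and `n_neg` negative PNGs (negatives alternate the
#' two constructions), the annotation CSV, and a JSON manifest echoing the
#' configuration and per-sample seeds. Fully deterministic for a fixed master
#' seed.
#'
#' @param n_pos,n_neg Sample counts.
#' @param cfg A [phantom_config()].
#' @param out_dir Output directory (created if missing).
#' @param seed Master seed.
#' @return Invisibly, the manifest list.
#' @export
generate_dataset <- function(n_pos, n_neg = 0, cfg = phantom_config(),
                             out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  samples <- generate_samples(n_pos, n_neg, cfg, seed)
  for (s in samples)
    write_image(s$image, file.path(out_dir, paste0(s$annotation$image_id, ".png")))
  anns <- lapply(samples, `[[`, "annotation")
  write_annotations(anns, file.path(out_dir, "annotations.csv"))
  manifest <- list(
    n_pos = n_pos, n_neg = n_neg, master_seed = seed,
    config = unclass(cfg),
    samples = lapply(samples, function(s)
      list(image_id = s$annotation$image_id, seed = s$seed,
           is_negative = s$annotation$is_negative))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate phantom samples in memory
#'
#' Same sampling scheme as [generate_dataset()] without touching disk.
#'
#' @inheritParams generate_dataset
#' @return List of `"phantom_sample"` objects (positives first).
#' @export
generate_samples <- function(n_pos, n_neg = 0, cfg = phantom_config(),
                             seed = 1L) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_pos + n_neg))
  pos <- lapply(seq_len(n_pos), function(i)
    generate_phantom(cfg, seeds[i], sprintf("phantom_%04d", i)))
  neg <- if (n_neg > 0) lapply(seq_len(n_neg), function(j) {
    base <- generate_phantom(cfg, seeds[n_pos + j] %% 1000000L + 7L,
                             sprintf("negsrc_%04d", j))
    mode <- if (j %% 2 == 1) "remove_fill" else "random_crop"
    make_negative(base, mode, seeds[n_pos + j])
  }) else list()
  c(pos, neg)
}
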