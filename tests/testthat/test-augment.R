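ring_mask <- function(e, H, W, thickness = 3) {
  df <- fetalhc:::ellipse_distance_field(e, H, W)
  abs(df$d) <= thickness / 2
}

mask_iou <- function(m1, m2) sum(m1 & m2) / sum(m1 | m2)

test_that("identity and intensity-only augmentations leave geometry alone", {
  s <- generate_phantom(phantom_config(), 21)
  r0 <- augment(s, "rotate", 0)
  expect_equal(r0$annotation$ellipse, s$annotation$ellipse)
  g <- augment(s, "gamma", 1.3)
  expect_equal(g$annotation$ellipse, s$annotation$ellipse)
  # gamma < 1 brightens monotonically (values in (0,255) increase)
  mid <- s$image > 10 & s$image < 250
  g2 <- augment(s, "gamma", 0.5)
  expect_true(all(g2$image[mid] >= s$image[mid] - 1))
})

test_that("rotation transforms image and annotation consistently", {
  cfg <- phantom_config(speckle = 0, background_texture = 0,
                        gap_fraction = 0)
  for (phi in c(-30, 10, 30)) {
    s <- generate_phantom(cfg, 22)
    r <- augment(s, "rotate", phi)
    expect_equal(r$annotation$ellipse$theta,
                 (s$annotation$ellipse$theta - phi) %% 180)
    # the ring predicted by the transformed annotation overlays the
    # transformed pixels
    lit <- r$image > 100
    band <- ring_mask(r$annotation$ellipse, nrow(r$image), ncol(r$image),
                      cfg$ring_thickness + 2)
    expect_gt(sum(lit & band) / sum(lit), 0.9)
  }
})

test_that("scaling co-scales geometry and pixel size so HC is invariant", {
  cfg <- phantom_config(speckle = 0, background_texture = 0,
                        gap_fraction = 0, semi_axis_range = c(14, 20))
  s <- generate_phantom(cfg, 23)
  hc0 <- head_circumference(s$annotation$ellipse$a * s$annotation$pixel_size_mm,
                            s$annotation$ellipse$b * s$annotation$pixel_size_mm)
  for (sig in c(0.85, 1.0, 1.15)) {
    sc <- augment(s, "scale", sig)
    expect_equal(sc$annotation$ellipse$a, s$annotation$ellipse$a * sig)
    expect_equal(sc$annotation$pixel_size_mm,
                 s$annotation$pixel_size_mm / sig)
    hc1 <- head_circumference(
      sc$annotation$ellipse$a * sc$annotation$pixel_size_mm,
      sc$annotation$ellipse$b * sc$annotation$pixel_size_mm)
    expect_equal(hc1, hc0, tolerance = 1e-3)
    lit <- sc$image > 100
    band <- ring_mask(sc$annotation$ellipse, nrow(sc$image), ncol(sc$image),
                      cfg$ring_thickness + 2)
    if (sum(lit) > 0) expect_gt(sum(lit & band) / sum(lit), 0.85)
  }
})

test_that("horizontal flip mirrors the center and the orientation", {
  cfg <- phantom_config(speckle = 0, background_texture = 0,
                        gap_fraction = 0)
  s <- generate_phantom(cfg, 24)
  f <- augment(s, "flip", TRUE)
  W <- ncol(s$image)
  expect_equal(f$annotation$ellipse$cx, W - 1 - s$annotation$ellipse$cx)
  expect_equal(f$annotation$ellipse$theta,
               (180 - s$annotation$ellipse$theta) %% 180)
  lit <- f$image > 100
  band <- ring_mask(f$annotation$ellipse, nrow(f$image), W,
                    cfg$ring_thickness + 2)
  expect_gt(sum(lit & band) / sum(lit), 0.9)
  expect_identical(augment(s, "flip", FALSE)$image, s$image)
})

test_that("augmented annotations still round-trip through the codec", {
  cfg <- phantom_config(semi_axis_range = c(14, 22))
  ssr <- ssr_config()
  s <- generate_phantom(cfg, 25)
  for (aug in list(c("rotate", 20), c("scale", 1.1), c("flip", TRUE))) {
    a <- augment(s, aug[[1]], if (aug[[1]] == "flip") TRUE else
      as.numeric(aug[[2]]))
    ts <- encode_targets(a$annotation, 4L, dim(a$image))
    d <- decode_detections(targets_to_detection_output(ts, ssr), ssr)[[1]]
    expect_equal(d$ellipse$cx, a$annotation$ellipse$cx, tolerance = 1e-9)
    expect_equal(d$ellipse$a, a$annotation$ellipse$a, tolerance = 1e-9)
    expect_lt(abs(angle_diff(d$ellipse$theta, a$annotation$ellipse$theta)),
              0.1)
  }
})

test_that("grid expansion counts follow the mode", {
  s <- generate_phantom(phantom_config(semi_axis_range = c(14, 18)), 26)
  rot_only <- list(rotate = seq(-30, 30, by = 10))
  out <- expand_training_set(list(s), rot_only, mode = "single",
                             quiet = TRUE)
  expect_length(out, 7)
  expect_length(expand_training_set(list(s), list(), quiet = TRUE), 1)
  grid <- list(rotate = c(-10, 0, 10), gamma = c(0.8, 1.2),
               flip = c(FALSE, TRUE))
  out <- expand_training_set(rep(list(s), 2), grid, mode = "compose",
                             quiet = TRUE)
  expect_length(out, 2 * 3 * 2 * 2)
  out <- expand_training_set(rep(list(s), 2), grid, mode = "single",
                             quiet = TRUE)
  expect_length(out, 2 * (3 + 2 + 2))
  # full default grid cardinalities match the stated protocol
  g <- augmentation_grid()
  expect_equal(lengths(g), c(rotate = 7L, scale = 7L, gamma = 11L,
                             flip = 2L))
})
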