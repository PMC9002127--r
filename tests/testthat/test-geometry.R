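test_that("ellipse constructor enforces invariants", {
  e <- ellipse(10, 20, 5, 3, 190)
  expect_equal(e$theta, 10) # wraps into [0, 180)
  expect_error(ellipse(0, 0, 2, 3), "a >= b")
  expect_error(ellipse(0, 0, 2, -1), ">= 0")
})

test_that("Gaussian embedding matches eigenstructure of the ellipse", {
  # circle: rotation-invariant, sigma = r^2 I
  g <- ellipse_to_gaussian(ellipse(0, 0, 2, 2, 0))
  expect_equal(g$sigma, 4 * diag(2), tolerance = 1e-12)
  # axis-aligned: eigenvalues a^2, b^2 with major axis horizontal
  g <- ellipse_to_gaussian(ellipse(0, 0, 3, 1, 0))
  ev <- eigen(g$sigma, symmetric = TRUE)
  expect_equal(sort(ev$values), c(1, 9), tolerance = 1e-10)
  major <- ev$vectors[, which.max(ev$values)]
  expect_equal(abs(major), c(1, 0), tolerance = 1e-10)
  # degenerate ellipse rejected
  expect_error(ellipse_to_gaussian(ellipse(0, 0, 3, 0, 0)), "singular")
})

test_that("Gaussian embedding is rotation-equivariant and volume-exact", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(1, 2, 8); b <- runif(1, 1, a); th <- runif(1, 0, 150)
    phi <- runif(1, 0, 30)
    g1 <- ellipse_to_gaussian(ellipse(0, 0, a, b, (th + phi) %% 180))
    g0 <- ellipse_to_gaussian(ellipse(0, 0, a, b, th))
    R <- fetalhc:::rotmat(phi)
    expect_lt(max(abs(g1$sigma - R %*% g0$sigma %*% t(R))), 1e-8)
    expect_equal(det(g0$sigma), (a * b)^2, tolerance = 1e-8)
  }
})

test_that("KLD between Gaussians matches closed forms and is asymmetric", {
  gA <- gaussian2d(c(0, 0), 4 * diag(2))
  expect_equal(kld_gaussian(gA, gA), 0, tolerance = 1e-10)
  gB <- gaussian2d(c(2, 0), 4 * diag(2))
  # equal isotropic covariances: KL = |d|^2 / (2 sigma^2)
  expect_equal(kld_gaussian(gB, gA), 0.5, tolerance = 1e-12)
  gC <- gaussian2d(c(1, -1), matrix(c(5, 1, 1, 2), 2))
  expect_gt(abs(kld_gaussian(gC, gA) - kld_gaussian(gA, gC)), 1e-6)
  expect_gte(kld_gaussian(gC, gA), 0)
})

test_that("KLD loss hits the worked value and saturates monotonically", {
  p <- ellipse(2, 0, 2, 2, 0); t <- ellipse(0, 0, 2, 2, 0)
  expect_equal(kld_loss(p, t), 1 - 1 / (1 + log(1.5)), tolerance = 1e-6)
  expect_equal(kld_loss(t, t), 0, tolerance = 1e-9)
  prev <- -1
  for (dx in c(5, 20, 100, 1000)) {
    l <- kld_loss(ellipse(dx, 0, 2, 2, 0), t)
    expect_gt(l, prev); prev <- l
  }
  expect_lt(prev, 1)
})

test_that("KLD is invariant under a common rigid transform", {
  set.seed(5)
  for (i in 1:10) {
    e1 <- ellipse(runif(1, -5, 5), runif(1, -5, 5), runif(1, 3, 6),
                  runif(1, 1, 3), runif(1, 0, 180))
    e2 <- ellipse(runif(1, -5, 5), runif(1, -5, 5), runif(1, 3, 6),
                  runif(1, 1, 3), runif(1, 0, 180))
    phi <- runif(1, 0, 90); tr <- runif(2, -10, 10)
    move <- function(e) {
      R <- fetalhc:::rotmat(phi)
      p <- R %*% c(e$cx, e$cy) + tr
      ellipse(p[1], p[2], e$a, e$b, (e$theta + phi) %% 180)
    }
    expect_equal(kld_loss(move(e1), move(e2)), kld_loss(e1, e2),
                 tolerance = 1e-8)
  }
})

test_that("Ramanujan HC agrees with arc-length integration", {
  expect_equal(head_circumference(1, 1), 2 * pi, tolerance = 1e-12)
  expect_equal(head_circumference(2, 1), pi * (9 - sqrt(35)),
               tolerance = 1e-12)
  # degenerate segment: formula vs analytic limit 4a
  expect_equal(head_circumference(1, 0), pi * (3 - sqrt(3)),
               tolerance = 1e-12)
  for (ba in c(0.2, 0.4, 0.6, 0.8, 1)) {
    a <- 10; b <- ba * a
    expect_equal(head_circumference(a, b), numeric_perimeter(a, b),
                 tolerance = 5e-3)
  }
  expect_error(head_circumference(-1, 0), "non-negative")
})

test_that("enclosing box is tight and contains the rasterized ellipse", {
  b <- enclosing_box(ellipse(0, 0, 3, 2, 0))
  expect_equal(c(b$w, b$h), c(6, 4), tolerance = 1e-12)
  b <- enclosing_box(ellipse(0, 0, 3, 2, 90))
  expect_equal(c(b$w, b$h), c(4, 6), tolerance = 1e-12)
  b <- enclosing_box(ellipse(0, 0, 3, 2, 45))
  expect_equal(c(b$w, b$h), rep(2 * sqrt(6.5), 2), tolerance = 1e-12)
  set.seed(21)
  for (i in 1:10) {
    e <- ellipse(0, 0, runif(1, 3, 8), runif(1, 2, 3), runif(1, 0, 180))
    b <- enclosing_box(e)
    phi <- seq(0, 2 * pi, length.out = 2000)
    r <- fetalhc:::theta_to_psi(e$theta) * pi / 180
    px <- e$a * cos(phi) * cos(r) - e$b * sin(phi) * sin(r)
    py <- e$a * cos(phi) * sin(r) + e$b * sin(phi) * cos(r)
    expect_true(all(abs(px) <= b$w / 2 + 1e-9))
    expect_true(all(abs(py) <= b$h / 2 + 1e-9))
    # 1% shrink breaks containment
    expect_false(all(abs(px) <= 0.99 * b$w / 2) &&
                   all(abs(py) <= 0.99 * b$h / 2))
  }
})

test_that("rasterized IOU matches analytic cases and converges", {
  e <- ellipse(0, 0, 5, 3, 30)
  expect_equal(ellipse_iou(e, e), 1.0)
  # concentric circles r = 1, 2 -> area ratio 1/4
  expect_equal(ellipse_iou(ellipse(0, 0, 4, 4, 0), ellipse(0, 0, 8, 8, 0),
                           resolution = 8), 0.25, tolerance = 0.005)
  expect_equal(ellipse_iou(ellipse(0, 0, 2, 2, 0), ellipse(10, 0, 3, 3, 0)),
               0)
  set.seed(31)
  for (i in 1:5) {
    e1 <- ellipse(runif(1, -2, 2), runif(1, -2, 2), runif(1, 4, 7),
                  runif(1, 3, 4), runif(1, 0, 180))
    e2 <- ellipse(runif(1, -2, 2), runif(1, -2, 2), runif(1, 4, 7),
                  runif(1, 3, 4), runif(1, 0, 180))
    expect_lt(abs(ellipse_iou(e1, e2, 8) - ellipse_iou(e1, e2, 16)), 0.005)
  }
  expect_error(ellipse_iou(e, ellipse(0, 0, 1, 0, 0)), "zero-area")
})
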