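#' Oriented ellipse
#'
#' The unit of annotation and prediction: an ellipse in image coordinates
#' (x right, y down, 0-based pixel centers) with semi-axes in pixels and an
#' orientation angle in degrees.
#'
#' @param cx,cy Center, pixels.
#' @param a Semi-major axis, pixels (`a > 0`).
#' @param b Semi-minor axis, pixels (`0 <= b <= a`).
#' @param theta Orientation in degrees in `[0, 180)`: the angle between the
#'   short axis of the ellipse and the vertical direction of the image. In the
#'   image frame this equals the angle of the major axis from the +x axis;
#'   [theta_to_psi()] owns that mapping.
#' @return An object of class `"ellipse"` (a named list).
#' @examples
#' e <- ellipse(100, 80, a = 40, b = 30, theta = 25)
#' head_circumference(e$a * 0.1, e$b * 0.1) # HC in mm at 0.1 mm/px
#' @export
ellipse <- function(cx, cy, a, b, theta = 0) {
  stopifnot(is.finite(cx), is.finite(cy), is.finite(a), is.finite(b),
            is.finite(theta))
  if (a < b) stop("ellipse: semi-major axis 'a' must satisfy a >= b")
  if (b < 0) stop("ellipse: semi-minor axis 'b' must be >= 0")
  theta <- theta %% 180
  structure(list(cx = cx, cy = cy, a = a, b = b, theta = theta),
            class = "ellipse")
}

#' @export
format.ellipse <- function(x, ...) {
  sprintf("<ellipse c=(%.2f, %.2f) a=%.2f b=%.2f theta=%.2f deg>",
          x$cx, x$cy, x$a, x$b, x$theta)
}

#' @export
print.ellipse <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Convert the stored orientation to the major-axis angle
#'
#' `theta` is defined as the angle between the short axis and the vertical
#' image direction. With x right and y down, rotating the short axis by theta
#' from vertical rotates the long axis by the same amount from horizontal, so
#' the major-axis-from-+x angle psi equals theta. This function is the single
#' owner of that identity; all trigonometric code works with psi.
#'
#' @param theta Angle in degrees.
#' @return psi in degrees.
#' @export
theta_to_psi <- function(theta) theta

#' 2-D Gaussian
#'
#' @param mu Length-2 mean vector, pixels.
#' @param sigma 2x2 symmetric positive-definite covariance, pixels^2.
#' @return An object of class `"gaussian2d"`.
#' @export
gaussian2d <- function(mu, sigma) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  stopifnot(length(mu) == 2, all(dim(sigma) == c(2, 2)))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("gaussian2d: covariance must be symmetric")
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("gaussian2d: covariance must be positive definite")
  structure(list(mu = mu, sigma = (sigma + t(sigma)) / 2), class = "gaussian2d")
}

rotmat <- function(psi_deg) {
  r <- psi_deg * pi / 180
  matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
}

#' Embed an oriented ellipse as a 2-D Gaussian
#'
#' The ellipse `(cx, cy, a, b, theta)` becomes `N(mu, Sigma)` with
#' `mu = (cx, cy)` and `Sigma^(1/2) = R(psi) diag(a, b) R(psi)'`, so that the
#' one-sigma contour of the Gaussian is the ellipse itself and
#' `det(Sigma^(1/2)) = a * b`.
#'
#' @param e An [ellipse()].
#' @return A [gaussian2d()].
#' @export
ellipse_to_gaussian <- function(e) {
  stopifnot(inherits(e, "ellipse"))
  if (e$b <= 0)
    stop("ellipse_to_gaussian: degenerate ellipse (b = 0) has singular covariance")
  R <- rotmat(theta_to_psi(e$theta))
  M <- R %*% diag(c(e$a, e$b)) %*% t(R)
  gaussian2d(c(e$cx, e$cy), M %*% M)
}

#' Kullback-Leibler divergence between two 2-D Gaussians
#'
#' `KL(p || t) = 1/2 (mu_p - mu_t)' St^-1 (mu_p - mu_t) + 1/2 tr(St^-1 Sp)
#'  + 1/2 ln(|St| / |Sp|) - 1`. Non-negative; zero iff the Gaussians coincide.
#'
#' @param p,t [gaussian2d()] objects (prediction, target).
#' @return Non-negative scalar.
#' @export
kld_gaussian <- function(p, t) {
  stopifnot(inherits(p, "gaussian2d"), inherits(t, "gaussian2d"))
  dt <- det(t$sigma)
  dp <- det(p$sigma)
  if (dt <= 0) stop("kld_gaussian: singular target covariance")
  ti <- solve(t$sigma)
  d <- p$mu - t$mu
  as.numeric(0.5 * (t(d) %*% ti %*% d) + 0.5 * sum(diag(ti %*% p$sigma)) +
               0.5 * log(dt / dp) - 1)
}

#' KLD regression loss between two oriented ellipses
#'
#' Both ellipses are embedded as 2-D Gaussians and the divergence is squashed
#' into `[0, 1)`: `L = 1 - 1 / (1 + ln(Dkl + 1))` (natural log). Strictly
#' increasing in the divergence and zero iff the ellipses are identical, so a
#' single scalar couples center, axis and angle errors.
#'
#' @param p,t Predicted and target [ellipse()] objects.
#' @return Loss in `[0, 1)`.
#' @export
kld_loss <- function(p, t) {
  dkl <- kld_gaussian(ellipse_to_gaussian(p), ellipse_to_gaussian(t))
  dkl <- max(dkl, 0) # guard tiny negative round-off at identity
  1 - 1 / (1 + log(dkl + 1))
}

#' Head circumference from semi-axes (Ramanujan perimeter approximation)
#'
#' `HC = pi * (3 (a + b) - sqrt((3 a + b) (a + 3 b)))`. Exact for circles and
#' within 0.5\% of the true elliptic perimeter for aspect ratios down to
#' b/a = 0.2, far below anything a fetal skull presents. Callers convert
#' pixels to mm with the pixel size before calling.
#'
#' @param a,b Semi-major and semi-minor axes, mm.
#' @return Perimeter, mm.
#' @examples
#' head_circumference(1, 1) # 2 * pi
#' @export
head_circumference <- function(a, b) {
  if (any(a < 0) || any(b < 0))
    stop("head_circumference: semi-axes must be non-negative")
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Smallest axis-aligned box enclosing an oriented ellipse
#'
#' @param e An [ellipse()].
#' @return Object of class `"aabox"` with fields `bx, by` (center, pixels) and
#'   `w, h` (full width and height, pixels).
#' @export
enclosing_box <- function(e) {
  stopifnot(inherits(e, "ellipse"))
  r <- theta_to_psi(e$theta) * pi / 180
  w <- 2 * sqrt(e$a^2 * cos(r)^2 + e$b^2 * sin(r)^2)
  h <- 2 * sqrt(e$a^2 * sin(r)^2 + e$b^2 * cos(r)^2)
  structure(list(bx = e$cx, by = e$cy, w = w, h = h), class = "aabox")
}

# Squared elliptical radius of points relative to an ellipse: 1 on the contour.
ellipse_radius2 <- function(e, x, y) {
  r <- theta_to_psi(e$theta) * pi / 180
  u <- (x - e$cx) * cos(r) + (y - e$cy) * sin(r)
  v <- -(x - e$cx) * sin(r) + (y - e$cy) * cos(r)
  (u / e$a)^2 + (v / e$b)^2
}

#' Rasterized IOU of two oriented ellipses
#'
#' Exact rotated-ellipse overlap has no convenient closed form, so this is a
#' membership-test oracle: both ellipses are tested on a regular grid covering
#' the union of their enclosing boxes and IOU is the cell-count ratio. Used
#' for evaluation matching and as the geometric ground truth in tests.
#'
#' @param e1,e2 [ellipse()] objects with positive area.
#' @param resolution Grid cells per pixel along each axis (default 4). Each
#'   ellipse should cover at least ~100 cells; the default does so for any
#'   ellipse with semi-axes above ~3 px.
#' @return IOU in `[0, 1]`.
#' @export
ellipse_iou <- function(e1, e2, resolution = 4) {
  stopifnot(inherits(e1, "ellipse"), inherits(e2, "ellipse"))
  if (e1$a * e1$b <= 0 || e2$a * e2$b <= 0)
    stop("ellipse_iou: zero-area ellipse")
  b1 <- enclosing_box(e1)
  b2 <- enclosing_box(e2)
  x0 <- min(b1$bx - b1$w / 2, b2$bx - b2$w / 2)
  x1 <- max(b1$bx + b1$w / 2, b2$bx + b2$w / 2)
  y0 <- min(b1$by - b1$h / 2, b2$by - b2$h / 2)
  y1 <- max(b1$by + b1$h / 2, b2$by + b2$h / 2)
  step <- 1 / resolution
  xs <- seq(x0 + step / 2, x1, by = step)
  ys <- seq(y0 + step / 2, y1, by = step)
  gx <- rep(xs, times = length(ys))
  gy <- rep(ys, each = length(xs))
  in1 <- ellipse_radius2(e1, gx, gy) <= 1
  in2 <- ellipse_radius2(e2, gx, gy) <= 1
  uni <- sum(in1 | in2)
  if (uni == 0) return(0)
  sum(in1 & in2) / uni
}

#' IOU of two axis-aligned boxes
#'
#' @param b1,b2 `"aabox"` objects.
#' @return IOU in `[0, 1]`.
#' @export
box_iou <- function(b1, b2) {
  ix <- max(0, min(b1$bx + b1$w / 2, b2$bx + b2$w / 2) -
              max(b1$bx - b1$w / 2, b2$bx - b2$w / 2))
  iy <- max(0, min(b1$by + b1$h / 2, b2$by + b2$h / 2) -
              max(b1$by - b1$h / 2, b2$by - b2$h / 2))
  inter <- ix * iy
  inter / (b1$w * b1$h + b2$w * b2$h - inter)
}
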