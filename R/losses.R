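#' Variant focal loss for the center heatmap
#'
#' Pixelwise penalty-reduced focal loss: at ground-truth centers (`P = 1`)
#' the term is `(1 - rho)^alpha log(rho)`; elsewhere `(1 - P)^beta rho^alpha
#' log(1 - rho)` down-weights pixels near (but not at) a center. Summed over
#' pixels, negated and divided by the number of objects (floored at 1 so
#' negative images are well-defined).
#'
#' @param pred Predicted heatmap, values in (0, 1); clipped to
#'   `(eps, 1 - eps)` internally.
#' @param gt Ground-truth heatmap in `[0, 1]` (1 exactly at centers).
#' @param n_objects Number of objects `N` (min 1).
#' @param alpha,beta Focusing exponents (defaults 2 and 4).
#' @param eps Clipping epsilon (default 1e-7).
#' @return Non-negative scalar.
#' @export
focal_loss <- function(pred, gt, n_objects, alpha = 2, beta = 4, eps = 1e-7) {
  if (!all(dim(pred) == dim(gt))) stop("focal_loss: shape mismatch")
  n <- max(1, n_objects)
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- gt >= 1
  term <- ifelse(pos,
                 (1 - p)^alpha * log(p),
                 (1 - gt)^beta * p^alpha * log(1 - p))
  -sum(term) / n
}

# dL/d pred for focal_loss (same clipping); used by the training loop and
# checked against numerical differentiation in the tests.
focal_loss_grad <- function(pred, gt, n_objects, alpha = 2, beta = 4,
                            eps = 1e-7) {
  n <- max(1, n_objects)
  p <- pmin(pmax(pred, eps), 1 - eps)
  pos <- gt >= 1
  g <- ifelse(pos,
              alpha * (1 - p)^(alpha - 1) * log(p) - (1 - p)^alpha / p,
              (1 - gt)^beta * (-alpha * p^(alpha - 1) * log(1 - p) +
                                 p^alpha / (1 - p)))
  inside <- pred > eps & pred < 1 - eps
  g * inside / n
}

#' Smooth L1 (Huber) penalty
#'
#' `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise; continuous with continuous
#' first derivative, gradient magnitude bounded by 1.
#'
#' @param x Residual(s).
#' @return Elementwise penalty, same shape as `x`.
#' @export
smooth_l1 <- function(x) {
  ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
}

# Derivative of smooth_l1.
smooth_l1_grad <- function(x) {
  ifelse(abs(x) < 1, x, sign(x))
}

#' Per-object regression losses at ground-truth centers
#'
#' Offset, semi-axis and angle residuals are gathered one per object at its
#' center cell and penalized with smooth L1, averaged over objects (and summed
#' over the two components for offset/axes). The angle residual uses the
#' minimal circular difference by default (see [angle_diff()]).
#'
#' @param offset_residuals N x 2 matrix of predicted-minus-target offsets.
#' @param axes_residuals N x 2 matrix of predicted-minus-target semi-axes, px.
#' @param angle_pred,angle_gt Length-N decoded and target angles, degrees.
#' @param kld Length-N per-object KLD losses (already in `[0, 1)`), or NULL.
#' @param circular_angle Use circular angle difference (default TRUE).
#' @return List with `offset`, `axes`, `angle`, `kld` scalar terms.
#' @export
regression_losses <- function(offset_residuals = NULL, axes_residuals = NULL,
                              angle_pred = NULL, angle_gt = NULL, kld = NULL,
                              circular_angle = TRUE) {
  term <- function(r) if (is.null(r) || length(r) == 0) 0 else
    sum(smooth_l1(r)) / max(1, if (is.matrix(r)) nrow(r) else length(r))
  ang <- if (is.null(angle_pred)) 0 else {
    d <- angle_diff(angle_pred, angle_gt, circular = circular_angle)
    mean(smooth_l1(d))
  }
  list(offset = term(offset_residuals),
       axes = term(axes_residuals),
       angle = ang,
       kld = if (is.null(kld) || length(kld) == 0) 0 else mean(kld))
}

#' Compose the total training objective
#'
#' The total is the (optionally weighted) sum of the heatmap focal term, the
#' offset, semi-axis and angle smooth-L1 terms, and the KLD term. The axes
#' term is included by default; `include_axes` preserves the alternative
#' reading in which it is folded elsewhere. Ablation flags zero out the SSR
#' angle and KLD terms to reproduce the three objective variants
#' (smooth-L1 only; + SSR; + SSR + KLD).
#'
#' @param parts List with `heat`, `offset`, `axes`, `angle`, `kld` scalars.
#' @param weights Named numeric per-term weights (default all 1).
#' @param include_axes Include the axes term in the total (default TRUE).
#' @param use_ssr,use_kld Ablation flags (default TRUE).
#' @return Object of class `"loss_breakdown"`: the five terms (after
#'   ablation) plus `total`.
#' @export
total_loss <- function(parts,
                       weights = c(heat = 1, offset = 1, axes = 1,
                                   angle = 1, kld = 1),
                       include_axes = TRUE, use_ssr = TRUE, use_kld = TRUE) {
  nm <- c("heat", "offset", "axes", "angle", "kld")
  for (f in nm) {
    v <- parts[[f]]
    if (is.null(v)) parts[[f]] <- 0
    else if (is.nan(v) || is.na(v) || !is.finite(v))
      stop("total_loss: non-finite term '", f, "'")
  }
  w <- c(heat = 1, offset = 1, axes = 1, angle = 1, kld = 1)
  w[names(weights)] <- weights
  if (!include_axes) w["axes"] <- 0
  if (!use_ssr) w["angle"] <- 0
  if (!use_kld) w["kld"] <- 0
  terms <- vapply(nm, function(f) w[[f]] * parts[[f]], numeric(1))
  structure(as.list(c(terms, total = sum(terms))), class = "loss_breakdown")
}

#' @export
format.loss_breakdown <- function(x, ...) {
  sprintf("Lh=%.4f Lo=%.4f Laxes=%.4f Ltheta=%.4f Lreg=%.4f total=%.4f",
          x$heat, x$offset, x$axes, x$angle, x$kld, x$total)
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
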