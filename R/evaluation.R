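#' Mean absolute error and mean error of HC measurements
#'
#' `MAE = mean(|pred - gt|)`, `ME = mean(pred - gt)` (sign convention:
#' prediction minus ground truth), each with a standard deviation (sample sd
#' by default, population sd available for completeness).
#'
#' @param pred_hc,gt_hc Equal-length numeric vectors, mm.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return List with `mae`, `mae_sd`, `me`, `me_sd` (mm).
#' @export
mae_me <- function(pred_hc, gt_hc, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(pred_hc) != length(gt_hc))
    stop("mae_me: length mismatch")
  if (length(pred_hc) < 1) stop("mae_me: need at least one pair")
  d <- pred_hc - gt_hc
  sdv <- function(x) {
    if (length(x) < 2) return(NA_real_)
    s <- stats::sd(x)
    if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
    s
  }
  list(mae = mean(abs(d)), mae_sd = sdv(abs(d)),
       me = mean(d), me_sd = sdv(d), sd_type = sd_type)
}

#' Rotated-ellipse average precision
#'
#' Predictions from all images are pooled and ranked by score; each is
#' matched greedily to the unmatched ground-truth ellipse of the same image
#' with the highest rasterized IOU, and is a true positive iff that IOU
#' reaches `iou_threshold`. AP is the area under the all-point interpolated
#' precision-recall curve (precision envelope).
#'
#' @param preds List (one per image) of lists of detections, each
#'   `list(ellipse = <ellipse>, score = <numeric>)`.
#' @param gts List (one per image) of lists of ground-truth [ellipse()]s
#'   (possibly empty).
#' @param iou_threshold Match threshold (default 0.5, the usual detection
#'   convention).
#' @param resolution Raster resolution for [ellipse_iou()].
#' @return AP in `[0, 1]`.
#' @export
average_precision <- function(preds, gts, iou_threshold = 0.5,
                              resolution = 4) {
  stopifnot(length(preds) == length(gts),
            iou_threshold > 0, iou_threshold < 1)
  n_gt <- sum(lengths(gts))
  if (n_gt == 0) stop("average_precision: no ground truth anywhere")
  rows <- list()
  for (i in seq_along(preds))
    for (d in preds[[i]])
      rows[[length(rows) + 1]] <- list(img = i, score = d$score,
                                       ellipse = d$ellipse)
  if (length(rows) == 0) return(0)
  ord <- order(vapply(rows, `[[`, numeric(1), "score"), decreasing = TRUE)
  matched <- lapply(gts, function(g) rep(FALSE, length(g)))
  tp <- numeric(length(rows)); fp <- numeric(length(rows))
  for (r in seq_along(ord)) {
    det <- rows[[ord[r]]]
    g <- gts[[det$img]]
    best <- 0; best_j <- 0
    for (j in seq_along(g)) {
      if (matched[[det$img]][j]) next
      iou <- ellipse_iou(det$ellipse, g[[j]], resolution)
      if (iou > best) { best <- iou; best_j <- j }
    }
    if (best_j > 0 && best >= iou_threshold) {
      tp[r] <- 1
      matched[[det$img]][best_j] <- TRUE
    } else fp[r] <- 1
  }
  ctp <- cumsum(tp); cfp <- cumsum(fp)
  recall <- ctp / n_gt
  precision <- ctp / (ctp + cfp)
  ap_from_pr(recall, precision)
}

# Area under the all-point interpolated PR curve.
ap_from_pr <- function(recall, precision) {
  r <- c(0, recall)
  p <- c(0, precision)
  # precision envelope: running max from the right
  for (i in (length(p) - 1):1) p[i] <- max(p[i], p[i + 1])
  sum(diff(r) * p[-1])
}

#' Bland-Altman agreement between predicted and reference HC
#'
#' Mean difference (bias) and mean +- 1.96 sd limits of agreement, plus the
#' per-case (mean, difference) pairs for the scatter plot.
#'
#' @param pred_hc,gt_hc Paired measurements, mm (n >= 2).
#' @return List with `mean_diff`, `loa_low`, `loa_high` (mm) and a
#'   `points` data frame (`mean`, `diff`).
#' @export
bland_altman <- function(pred_hc, gt_hc) {
  if (length(pred_hc) != length(gt_hc)) stop("bland_altman: length mismatch")
  if (length(pred_hc) < 2) stop("bland_altman: need at least two pairs")
  d <- pred_hc - gt_hc
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
       points = data.frame(mean = (pred_hc + gt_hc) / 2, diff = d))
}

#' Evaluate predictions against ground truth
#'
#' Composes [mae_me()], [average_precision()] and [bland_altman()] into one
#' report over paired per-image results.
#'
#' @param preds Per-image detection lists (see [average_precision()]).
#' @param gts Per-image ground-truth ellipse lists.
#' @param pred_hc,gt_hc Paired HC values, mm, for the detected subset.
#' @param iou_threshold AP matching threshold.
#' @return Object of class `"eval_report"`.
#' @export
eval_report <- function(preds, gts, pred_hc, gt_hc, iou_threshold = 0.5) {
  err <- mae_me(pred_hc, gt_hc)
  ba <- if (length(pred_hc) >= 2) bland_altman(pred_hc, gt_hc) else NULL
  structure(list(
    mae_mm = err$mae, mae_sd_mm = err$mae_sd,
    me_mm = err$me, me_sd_mm = err$me_sd,
    ap = average_precision(preds, gts, iou_threshold),
    bland_altman = ba,
    n = length(pred_hc),
    interpolation = "all-point"
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("HC evaluation over %d cases\n", x$n))
  cat(sprintf("  MAE: %.3f +- %.3f mm\n", x$mae_mm, x$mae_sd_mm))
  cat(sprintf("  ME:  %.3f +- %.3f mm\n", x$me_mm, x$me_sd_mm))
  cat(sprintf("  AP:  %.4f\n", x$ap))
  if (!is.null(x$bland_altman))
    cat(sprintf("  Bland-Altman: bias %.3f mm, LoA [%.3f, %.3f] mm\n",
                x$bland_altman$mean_diff, x$bland_altman$loa_low,
                x$bland_altman$loa_high))
  invisible(x)
}
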