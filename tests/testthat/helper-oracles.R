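# Independent oracles used across the suite; deliberately naive.

# Ellipse perimeter by numerical arc-length integration.
numeric_perimeter <- function(a, b, n = 20000) {
  phi <- seq(0, 2 * pi, length.out = n + 1)
  dens <- sqrt(a^2 * sin(phi)^2 + b^2 * cos(phi)^2)
  sum((dens[-1] + dens[-(n + 1)]) / 2 * diff(phi))
}

# Average precision by exhaustive enumeration: every prediction may match
# any unmatched same-image GT with IOU >= threshold; all consistent
# assignments are enumerated and the best achievable AP is returned.
brute_force_ap <- function(preds, gts, iou_threshold = 0.5, resolution = 4) {
  n_gt <- sum(lengths(gts))
  rows <- list()
  for (i in seq_along(preds))
    for (d in preds[[i]])
      rows[[length(rows) + 1]] <- list(img = i, score = d$score,
                                       ellipse = d$ellipse)
  if (length(rows) == 0) return(0)
  ord <- order(vapply(rows, `[[`, numeric(1), "score"), decreasing = TRUE)
  rows <- rows[ord]
  # feasible matches per prediction
  cand <- lapply(rows, function(r) {
    js <- c()
    for (j in seq_along(gts[[r$img]]))
      if (ellipse_iou(r$ellipse, gts[[r$img]][[j]], resolution) >=
          iou_threshold) js <- c(js, j)
    js
  })
  best <- -1
  assign_rec <- function(k, used, labels) {
    if (k > length(rows)) {
      ctp <- cumsum(labels); cfp <- cumsum(1 - labels)
      rec <- ctp / n_gt; prec <- ctp / (ctp + cfp)
      ap <- fetalhc:::ap_from_pr(rec, prec)
      if (ap > best) best <<- ap
      return(invisible(NULL))
    }
    key <- paste0(rows[[k]]$img, ":")
    feas <- cand[[k]]
    feas <- feas[!(paste0(key, feas) %in% used)]
    for (j in feas)
      assign_rec(k + 1, c(used, paste0(key, j)), c(labels, 1))
    assign_rec(k + 1, used, c(labels, 0))
  }
  assign_rec(1, character(0), numeric(0))
  best
}

# A quick positive phantom + its encoded targets, reused in codec tests.
make_phantom_fixture <- function(seed = 1, size = 64) {
  pc <- phantom_config(image_size = c(size, size),
                       semi_axis_range = c(size * 0.15, size * 0.3),
                       ring_thickness = 2)
  generate_phantom(pc, seed)
}
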