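# Optional adapter for the HC18 grand-challenge layout: a CSV of filenames
# and pixel sizes plus one contour ("annotation") PNG per training image.
# The adapter converts that layout into this package's annotation dialect by
# fitting an ellipse to each contour. It is a convenience for real data and
# is never used by the test fixtures, which generate exact annotations.

#' Direct least-squares ellipse fit
#'
#' Fits a conic constrained to be an ellipse to scattered contour points
#' (numerically stable Halir-Flusser formulation of the Fitzgibbon direct
#' least-squares method), then converts it to geometric parameters.
#'
#' @param x,y Point coordinates, pixels (>= 6 points, not collinear).
#' @return An [ellipse()].
#' @export
fit_ellipse_lsq <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 6)
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- -solve(S3, t(S2))
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (length(ok) == 0) stop("fit_ellipse_lsq: no elliptic solution")
  a1 <- evec[, ok[1]]
  coef <- c(a1, Tm %*% a1)  # A, B, C, D, E, F in scaled frame
  conic_to_ellipse(coef, mx, my, sc)
}

# Convert conic A x^2 + B x y + C y^2 + D x + E y + F = 0 (in the scaled,
# centered frame) back to image-frame geometric parameters.
conic_to_ellipse <- function(cf, mx, my, sc) {
  A <- cf[1]; B <- cf[2]; C <- cf[3]; D <- cf[4]; E <- cf[5]; F <- cf[6]
  den <- B^2 - 4 * A * C
  if (den >= 0) stop("conic_to_ellipse: not an ellipse")
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  # centered conic: (p - c)' Q (p - c) + Fc = 0 with Q = [[A, B/2], [B/2, C]];
  # semi-axes follow from -Fc / eigenvalues, orientation from the major
  # eigenvector (sign of Q is arbitrary, so work through -Fc/lambda)
  Fc <- F + (D * cx + E * cy) / 2
  Q <- matrix(c(A, B / 2, B / 2, C), 2)
  ev <- eigen(Q, symmetric = TRUE)
  r2 <- -Fc / ev$values
  if (any(r2 <= 0)) stop("conic_to_ellipse: not an ellipse")
  major <- which.max(r2)
  a <- sqrt(max(r2)); b <- sqrt(min(r2))
  v <- ev$vectors[, major]
  psi <- atan2(v[2], v[1]) * 180 / pi
  # back to image frame: the fit ran on (p - m) / sc
  ellipse(cx * sc + mx, cy * sc + my, a * sc, b * sc, psi %% 180)
}

#' Load HC18-style annotations
#'
#' Reads the challenge CSV (`filename`, `pixel size(mm)` columns) and, for
#' each row, the matching `*_Annotation.png` contour image from
#' `annotation_images_dir`; bright contour pixels are fitted with
#' [fit_ellipse_lsq()] and emitted as this package's [annotation()] objects
#' (semi-axes in pixels). Unreadable files and malformed rows are skipped
#' with a warning and counted.
#'
#' @param csv_path Path to the challenge CSV.
#' @param annotation_images_dir Directory holding the contour PNGs.
#' @return List of [annotation()] objects; attribute `skipped` counts the
#'   rows that could not be converted.
#' @export
load_hc18_annotations <- function(csv_path, annotation_images_dir) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                        check.names = FALSE)
  ps_col <- grep("pixel", names(df), ignore.case = TRUE, value = TRUE)[1]
  fn_col <- grep("filename", names(df), ignore.case = TRUE, value = TRUE)[1]
  if (is.na(ps_col) || is.na(fn_col))
    stop("load_hc18_annotations: CSV lacks filename / pixel size columns")
  out <- list(); skipped <- 0L
  for (i in seq_len(nrow(df))) {
    fn <- df[[fn_col]][i]
    ps <- suppressWarnings(as.numeric(df[[ps_col]][i]))
    ann_path <- file.path(annotation_images_dir,
                          sub("\\.png$", "_Annotation.png", fn))
    res <- tryCatch({
      if (!is.finite(ps) || ps <= 0) stop("bad pixel size")
      img <- read_image(ann_path)
      pts <- which(img > 127, arr.ind = TRUE)
      if (nrow(pts) < 6) stop("too few contour pixels")
      e <- fit_ellipse_lsq(pts[, 2] - 1, pts[, 1] - 1)  # 0-based (x, y)
      annotation(sub("\\.png$", "", fn), e, ps)
    }, error = function(err) {
      warning("load_hc18_annotations: skipping ", fn, " (",
              conditionMessage(err), ")", call. = FALSE)
      NULL
    })
    if (is.null(res)) skipped <- skipped + 1L else out[[length(out) + 1]] <- res
  }
  if (length(out) == 0 && nrow(df) == 0)
    warning("load_hc18_annotations: no rows found")
  attr(out, "skipped") <- skipped
  out
}
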