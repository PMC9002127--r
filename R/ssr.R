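#' Soft stagewise regression (SSR) configuration for the rotation angle
#'
#' The angle range `V = [0, 180)` degrees is binned hierarchically: stage 1
#' splits it into `S1` coarse bins, stage 2 splits one coarse bin into `S2`,
#' and so on. Defaults `(18, 10, 10)` give bin widths 10, 1 and 0.1 degrees.
#'
#' @param stages Integer vector of per-stage bin counts, each >= 2.
#' @param V Angle range in degrees (default 180).
#' @return Object of class `"ssr_config"`.
#' @export
ssr_config <- function(stages = c(18L, 10L, 10L), V = 180) {
  stopifnot(all(stages >= 2), V > 0)
  structure(list(stages = as.integer(stages), V = V), class = "ssr_config")
}

# Bin widths per stage given the per-stage scale modifiers Delta:
# omega_k = V / prod_{j<=k} s_j (1 + Delta_j).
ssr_widths <- function(cfg, delta = NULL) {
  K <- length(cfg$stages)
  if (is.null(delta)) delta <- rep(0, K)
  cfg$V / cumprod(cfg$stages * (1 + delta))
}

#' Decode an SSR prediction into an angle
#'
#' Each stage contributes its expected (probability-weighted) bin index,
#' shifted per bin by `eta` and scaled through widths that depend on the
#' per-stage modifiers `Delta`:
#' `theta = sum_k sum_i p_i^(k) (i + eta_i^(k)) * V / prod_{j<=k} s_j (1 + Delta_j)`.
#' Soft mixing over bins makes the decode differentiable, so the angle can be
#' supervised directly with a smooth-L1 loss.
#'
#' @param pred List with `probs` (list of per-stage probability vectors,
#'   each summing to 1), `delta` (numeric, one per stage, in (-1, 1)) and
#'   `eta` (list of per-stage, per-bin offsets in (-1, 1)).
#' @param cfg An [ssr_config()].
#' @param wrap Wrap the result into `[0, V)` (default TRUE). Training code
#'   uses `wrap = FALSE` so the decode stays smooth.
#' @return Angle in degrees.
#' @export
ssr_decode <- function(pred, cfg = ssr_config(), wrap = TRUE) {
  K <- length(cfg$stages)
  if (length(pred$probs) != K)
    stop("ssr_decode: expected ", K, " stages, got ", length(pred$probs))
  if (is.null(pred$delta)) pred$delta <- rep(0, K)
  if (is.null(pred$eta)) pred$eta <- lapply(cfg$stages, function(s) rep(0, s))
  for (k in seq_len(K)) {
    if (length(pred$probs[[k]]) != cfg$stages[k] ||
        length(pred$eta[[k]]) != cfg$stages[k])
      stop("ssr_decode: stage ", k, " shape mismatch")
    if (abs(sum(pred$probs[[k]]) - 1) > 1e-6)
      stop("ssr_decode: stage ", k, " probabilities do not sum to 1")
  }
  w <- ssr_widths(cfg, pred$delta)
  theta <- 0
  for (k in seq_len(K)) {
    i <- seq_len(cfg$stages[k]) - 1
    theta <- theta + sum(pred$probs[[k]] * (i + pred$eta[[k]])) * w[k]
  }
  if (wrap) theta %% cfg$V else theta
}

#' Reference (one-hot) SSR encoding of an angle
#'
#' Greedy coarse-to-fine binning with zero `Delta` and `eta`: the test-only
#' inverse of [ssr_decode()]. Quantization error is below the finest bin
#' width (0.1 degrees at the default configuration).
#'
#' @param theta Angle in degrees, `0 <= theta < V`.
#' @param cfg An [ssr_config()].
#' @return An SSR prediction list (see [ssr_decode()]).
#' @export
ssr_encode_reference <- function(theta, cfg = ssr_config()) {
  if (theta < 0 || theta >= cfg$V)
    stop("ssr_encode_reference: angle outside [0, V)")
  w <- ssr_widths(cfg)
  K <- length(cfg$stages)
  probs <- vector("list", K)
  rem <- theta
  for (k in seq_len(K)) {
    i <- min(floor(rem / w[k]), cfg$stages[k] - 1)
    p <- rep(0, cfg$stages[k]); p[i + 1] <- 1
    probs[[k]] <- p
    rem <- rem - i * w[k]
  }
  list(probs = probs, delta = rep(0, K),
       eta = lapply(cfg$stages, function(s) rep(0, s)))
}

#' Partial derivatives of the SSR decode
#'
#' Returns the gradient of the decoded (unwrapped) angle with respect to the
#' stage probabilities, the per-bin shifts `eta`, and the per-stage scale
#' modifiers `Delta`. Used by the training loop to push smooth-L1 and KLD
#' angle gradients through the decode.
#'
#' @param pred,cfg As in [ssr_decode()].
#' @return List `d_probs` (list per stage), `d_eta` (list per stage),
#'   `d_delta` (numeric per stage).
#' @keywords internal
#' @export
ssr_decode_grad <- function(pred, cfg = ssr_config()) {
  K <- length(cfg$stages)
  w <- ssr_widths(cfg, pred$delta)
  d_probs <- vector("list", K)
  d_eta <- vector("list", K)
  stage_sum <- numeric(K) # sum_i p_i (i + eta_i), per stage
  for (k in seq_len(K)) {
    i <- seq_len(cfg$stages[k]) - 1
    ibar <- i + pred$eta[[k]]
    d_probs[[k]] <- ibar * w[k]
    d_eta[[k]] <- pred$probs[[k]] * w[k]
    stage_sum[k] <- sum(pred$probs[[k]] * ibar)
  }
  # d omega_k / d Delta_j = -omega_k / (1 + Delta_j) for k >= j
  d_delta <- vapply(seq_len(K), function(j) {
    ks <- j:K
    -sum(stage_sum[ks] * w[ks]) / (1 + pred$delta[j])
  }, numeric(1))
  list(d_probs = d_probs, d_eta = d_eta, d_delta = d_delta)
}

#' Minimal circular difference between two angles
#'
#' The ellipse orientation lives on a 180-degree circle; the loss uses the
#' signed difference of smallest magnitude so that 179.9 vs 0.1 degrees costs
#' 0.2, not 179.8. The literal linear difference is available for comparison.
#'
#' @param pred,gt Angles in degrees.
#' @param period Circle period (default 180).
#' @param circular If FALSE, return the plain difference `pred - gt`.
#' @return Signed difference in `(-period/2, period/2]` (circular case).
#' @export
angle_diff <- function(pred, gt, period = 180, circular = TRUE) {
  d <- pred - gt
  if (!circular) return(d)
  ((d + period / 2) %% period) - period / 2
}
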