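# Training: momentum-SGD on the composed objective. The loss-side chain
# rules (focal -> sigmoid logit, smooth-L1 -> softplus/softmax/tanh, KLD ->
# decoded ellipse parameters) are assembled here; nn_backward() takes over
# from the raw head maps.

# 2-D Gaussian embedding from raw ellipse parameters (no ordering or class
# checks: used on predictions whose two axis channels may arrive unsorted).
gauss_raw <- function(cx, cy, a, b, theta) {
  r <- theta * pi / 180
  R <- matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
  M <- R %*% diag(c(a, b)) %*% t(R)
  list(mu = c(cx, cy), sigma = M %*% M)
}

kld_raw <- function(p, t) {
  ti <- solve(t$sigma)
  d <- p$mu - t$mu
  dkl <- as.numeric(0.5 * (t(d) %*% ti %*% d) +
                      0.5 * sum(diag(ti %*% p$sigma)) +
                      0.5 * log(det(t$sigma) / det(p$sigma)) - 1)
  1 - 1 / (1 + log(max(dkl, 0) + 1))
}

# KLD loss and its gradient wrt (cx, cy, a, b, theta) by central differences.
kld_loss_and_grad <- function(cx, cy, a, b, theta, gt_gauss) {
  f <- function(v) kld_raw(gauss_raw(v[1], v[2], v[3], v[4], v[5]), gt_gauss)
  v <- c(cx, cy, a, b, theta)
  val <- f(v)
  g <- numeric(5)
  for (i in 1:5) {
    h <- 1e-4 * max(1, abs(v[i]))
    if (i %in% 3:4) h <- min(h, v[i] / 2)  # keep axes positive
    vp <- v; vp[i] <- v[i] + h
    vm <- v; vm[i] <- v[i] - h
    g[i] <- (f(vp) - f(vm)) / (2 * h)
  }
  list(value = val, grad = g)
}

# Compute the batch loss breakdown and the gradients wrt the raw head maps.
batch_loss_grads <- function(model, fwd, targets, weights, include_axes,
                             use_ssr, use_kld, circular_angle = TRUE) {
  out <- fwd$out
  cfg <- model$cfg; ssr <- cfg$ssr
  s <- cfg$stride
  dmap <- dim(out$heatmap)
  ny <- dmap[1]; nx <- dmap[2]; N <- dmap[4]
  w <- c(heat = 1, offset = 1, axes = 1, angle = 1, kld = 1)
  w[names(weights)] <- weights
  if (!include_axes) w["axes"] <- 0
  if (!use_ssr) w["angle"] <- 0
  if (!use_kld) w["kld"] <- 0

  gt_heat <- array(0, dmap)
  for (n in seq_len(N)) gt_heat[, , 1, n] <- targets[[n]]$heatmap
  npos <- sum(vapply(targets, `[[`, integer(1), "n_objects"))
  nobj <- max(1L, npos)

  rho <- out$heatmap
  l_heat <- focal_loss(rho, gt_heat, nobj)
  dz_heat <- w["heat"] * focal_loss_grad(rho, gt_heat, nobj) * rho * (1 - rho)

  dz_off <- array(0, dim(out$offset))
  dz_axes <- array(0, dim(out$axes))
  dz_probs <- array(0, dim(out$ssr_probs))
  dz_eta <- array(0, dim(out$ssr_eta))
  dz_delta <- matrix(0, 3, N)
  l_off <- 0; l_axes <- 0; l_angle <- 0; l_kld <- 0

  for (n in seq_len(N)) {
    ts <- targets[[n]]
    if (ts$n_objects == 0) next
    ix <- ts$center_index["ix"]; iy <- ts$center_index["iy"]
    ix1 <- ix + 1L; iy1 <- iy + 1L

    po <- out$offset[iy1, ix1, , n]
    ro <- po - ts$offset
    l_off <- l_off + sum(smooth_l1(ro))
    d_po <- w["offset"] * smooth_l1_grad(ro) / npos

    pa <- out$axes[iy1, ix1, , n]
    ra <- pa - ts$axes
    l_axes <- l_axes + sum(smooth_l1(ra))
    d_pa <- w["axes"] * smooth_l1_grad(ra) / npos

    pred <- ssr_prediction_at(list(ssr_probs = out$ssr_probs[, , , n],
                                   ssr_eta = out$ssr_eta[, , , n],
                                   ssr_delta = out$ssr_delta[, n]),
                              iy1, ix1, ssr)
    th_raw <- ssr_decode(pred, ssr, wrap = FALSE)
    dth <- angle_diff(th_raw %% ssr$V, ts$angle, period = ssr$V,
                      circular = circular_angle)
    l_angle <- l_angle + smooth_l1(dth)
    d_theta <- w["angle"] * smooth_l1_grad(dth) / npos

    if (use_kld) {
      cxp <- (ix + po[1]) * s; cyp <- (iy + po[2]) * s
      kg <- kld_loss_and_grad(cxp, cyp, max(pa[1], 1e-2), max(pa[2], 1e-2),
                              th_raw %% ssr$V, ts$gt_gaussian)
      l_kld <- l_kld + kg$value
      d_po <- d_po + w["kld"] * kg$grad[1:2] * s / npos
      d_pa <- d_pa + w["kld"] * kg$grad[3:4] / npos
      d_theta <- d_theta + w["kld"] * kg$grad[5] / npos
    }

    dz_off[iy1, ix1, , n] <- d_po
    # softplus chain: y = softplus(z) => dz = dy * (1 - exp(-y))
    dz_axes[iy1, ix1, , n] <- d_pa * (1 - exp(-pmax(pa, 1e-8)))

    if (w["angle"] > 0 || (use_kld && w["kld"] > 0)) {
      g <- ssr_decode_grad(pred, ssr)
      ofs <- 0L
      for (k in seq_along(ssr$stages)) {
        rng <- ofs + seq_len(ssr$stages[k])
        p_k <- pred$probs[[k]]
        dLdp <- d_theta * g$d_probs[[k]]
        dz_probs[iy1, ix1, rng, n] <- p_k * (dLdp - sum(dLdp * p_k))
        dLde <- d_theta * g$d_eta[[k]]
        dz_eta[iy1, ix1, rng, n] <- dLde * (1 - pred$eta[[k]]^2)
        ofs <- ofs + ssr$stages[k]
      }
      dz_delta[, n] <- dz_delta[, n] +
        d_theta * g$d_delta * (1 - pred$delta^2)
    }
  }
  parts <- list(heat = l_heat,
                offset = l_off / npos_or_1(npos),
                axes = l_axes / npos_or_1(npos),
                angle = l_angle / npos_or_1(npos),
                kld = l_kld / npos_or_1(npos))
  breakdown <- total_loss(parts, weights = w, include_axes = include_axes,
                          use_ssr = use_ssr, use_kld = use_kld)
  list(breakdown = breakdown,
       dz = list(heatmap = dz_heat, offset = dz_off, axes = dz_axes,
                 ssr_probs = dz_probs, ssr_eta = dz_eta, delta = dz_delta))
}

npos_or_1 <- function(n) max(1L, n)

# Momentum-SGD step with global-norm gradient clipping.
sgd_update <- function(model, grads, state, lr, momentum = 0.9, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  scale <- if (is.finite(gn) && gn > clip) clip / gn else 1
  for (nm in names(grads)) {
    g <- grads[[nm]] * scale
    v <- state[[nm]]
    v <- if (is.null(v)) -lr * g else momentum * v - lr * g
    state[[nm]] <- v
    model$params[[nm]] <- model$params[[nm]] + v
  }
  invisible(NULL)
}

# One optimisation step on a prepared batch; returns the loss breakdown.
train_step <- function(model, x, targets, state, lr, momentum = 0.9,
                       weights = c(), include_axes = TRUE, use_ssr = TRUE,
                       use_kld = TRUE, circular_angle = TRUE) {
  fwd <- nn_forward(model, x, train = TRUE, want_cache = TRUE)
  bl <- batch_loss_grads(model, fwd, targets, weights, include_axes,
                         use_ssr, use_kld, circular_angle)
  grads <- nn_backward(model, fwd, bl$dz)
  sgd_update(model, grads, state, lr, momentum)
  bl$breakdown
}

# Stack sample images into an (H, W, 1, N) batch in [0, 1].
stack_images <- function(samples) {
  H <- nrow(samples[[1]]$image); W <- ncol(samples[[1]]$image)
  x <- array(0, c(H, W, 1, length(samples)))
  for (i in seq_along(samples)) x[, , 1, i] <- samples[[i]]$image / 255
  x
}

#' Train the detector
#'
#' Momentum-SGD (defaults lr 0.005, momentum 0.9) on the composed objective:
#' heatmap focal loss, offset/semi-axis smooth-L1, SSR angle smooth-L1, and
#' the KLD ellipse loss. One structured log line per epoch reports every
#' term, so ablations (`use_ssr`, `use_kld`, `include_axes`) are scriptable
#' and auditable from the log alone.
#'
#' @param samples List of `"phantom_sample"` objects (or any objects with
#'   `image` and `annotation` fields matching the model input size).
#' @param model An `"fh_model"`, or NULL to build one from `cfg`.
#' @param cfg A [model_config()] used when `model` is NULL.
#' @param epochs Number of passes over the data.
#' @param batch_size Mini-batch size (default 4, sized for CPU).
#' @param lr,momentum Optimiser settings.
#' @param weights Named per-term loss weights (default all 1).
#' @param include_axes,use_ssr,use_kld Objective flags (see [total_loss()]).
#' @param circular_angle Use the minimal circular angle difference.
#' @param seed Seed for shuffling, dropout and (if built here) init.
#' @param verbose Print the per-epoch loss line.
#' @return List with `model`, `history` (one row per epoch with every loss
#'   term) and the optimiser `state`.
#' @export
train_model <- function(samples, model = NULL, cfg = NULL, epochs = 5L,
                        batch_size = 4L, lr = 0.005, momentum = 0.9,
                        weights = c(), include_axes = TRUE, use_ssr = TRUE,
                        use_kld = TRUE, circular_angle = TRUE, seed = 1L,
                        verbose = TRUE) {
  if (is.null(model)) {
    if (is.null(cfg)) cfg <- preset_config("tiny")
    model <- build_model(cfg, seed = seed, quiet = !verbose)
  }
  H <- model$cfg$input_size[1]; W <- model$cfg$input_size[2]
  targets_all <- lapply(samples, function(sm)
    encode_targets(sm$annotation, model$cfg$stride, c(H, W)))
  state <- new.env(parent = emptyenv())
  history <- list()
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(samples))
      ep_terms <- c(heat = 0, offset = 0, axes = 0, angle = 0, kld = 0,
                    total = 0)
      nb <- 0
      for (b0 in seq(1, length(ord), by = batch_size)) {
        idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        x <- stack_images(samples[idx])
        bl <- train_step(model, x, targets_all[idx], state, lr, momentum,
                         weights, include_axes, use_ssr, use_kld,
                         circular_angle)
        ep_terms <- ep_terms + unlist(bl[c("heat", "offset", "axes",
                                           "angle", "kld", "total")])
        nb <- nb + 1
      }
      ep_terms <- ep_terms / nb
      history[[ep]] <- c(epoch = ep, ep_terms)
      if (verbose)
        message(sprintf(
          "epoch %d: Lh=%.4f Lo=%.4f Laxes=%.4f Ltheta=%.4f Lreg=%.4f total=%.4f",
          ep, ep_terms["heat"], ep_terms["offset"], ep_terms["axes"],
          ep_terms["angle"], ep_terms["kld"], ep_terms["total"]))
    }
  })
  list(model = model, history = as.data.frame(do.call(rbind, history)),
       state = state)
}
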