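micro_cfg <- function(mhsa = FALSE)
  model_config(input_size = c(32, 32), base_channels = 8,
               encoder_depth = 4, use_mhsa = mhsa, dropout = 0)

test_that("configuration contracts: stride, divisibility, head channels", {
  expect_error(model_config(input_size = c(100, 96)), "divisible by 32")
  cfg <- model_config(input_size = c(256, 256))
  m <- build_model(cfg, seed = 1, quiet = TRUE)
  x <- array(runif(256 * 256), c(256, 256, 1, 1))
  out <- nn_forward(m, x)$out
  expect_equal(dim(out$heatmap)[1:2], c(64, 64))
  expect_equal(dim(out$offset)[3], 2)
  expect_equal(dim(out$axes)[3], 2)
  expect_equal(dim(out$ssr_probs)[3], sum(ssr_config()$stages))
  expect_equal(dim(out$ssr_eta)[3], sum(ssr_config()$stages))
  expect_equal(dim(out$ssr_delta), c(3, 1))
  # tiny preset stays within a desk-scale parameter budget
  expect_lt(n_parameters(build_model(preset_config("tiny"), seed = 1,
                                     quiet = TRUE)), 2e6)
  # a five-stage encoder also honours the stride contract
  cfg5 <- model_config(input_size = c(64, 64), base_channels = 8,
                       encoder_depth = 5, use_mhsa = TRUE, dropout = 0)
  m5 <- build_model(cfg5, seed = 1, quiet = TRUE)
  o5 <- nn_forward(m5, array(runif(64 * 64), c(64, 64, 1, 1)))$out
  expect_equal(dim(o5$heatmap)[1:2], c(16, 16))
})

test_that("attention is shape-preserving and deformable falls back", {
  x <- array(runif(32 * 32), c(32, 32, 1, 2))
  m0 <- build_model(micro_cfg(FALSE), seed = 2, quiet = TRUE)
  m1 <- build_model(micro_cfg(TRUE), seed = 2, quiet = TRUE)
  o0 <- nn_forward(m0, x)$out; o1 <- nn_forward(m1, x)$out
  for (f in c("heatmap", "offset", "axes", "ssr_probs", "ssr_eta"))
    expect_equal(dim(o0[[f]]), dim(o1[[f]]))
  expect_warning(build_model(model_config(use_deformable = TRUE),
                             seed = 1, quiet = TRUE), "deformable")
})

test_that("forward output invariants hold for random weights", {
  m <- build_model(micro_cfg(TRUE), seed = 5, quiet = TRUE)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  out <- nn_forward(m, x)$out
  stages <- ssr_config()$stages
  ofs <- 0
  for (s in stages) {
    tot <- apply(out$ssr_probs[, , ofs + seq_len(s), , drop = FALSE],
                 c(1, 2, 4), sum)
    expect_true(all(abs(tot - 1) < 1e-5))
    ofs <- ofs + s
  }
  expect_true(all(out$axes > 0))
  expect_true(all(out$heatmap > 0 & out$heatmap < 1))
  expect_true(all(abs(out$ssr_delta) < 1))
  # eval-mode determinism: identical outputs for identical inputs
  out2 <- nn_forward(m, x)$out
  expect_identical(out, out2)
  expect_error(nn_forward(m, array(0, c(64, 64, 1, 1))), "does not match")
})

test_that("analytic gradients match numerical differentiation end-to-end", {
  set.seed(42)
  for (mh in c(FALSE, TRUE)) {
    m <- build_model(micro_cfg(mh), seed = 3, quiet = TRUE)
    pc <- phantom_config(image_size = c(32, 32), semi_axis_range = c(6, 10),
                         ring_thickness = 2)
    samples <- list(generate_phantom(pc, 11), generate_phantom(pc, 12))
    x <- fetalhc:::stack_images(samples)
    tg <- lapply(samples, function(sm)
      encode_targets(sm$annotation, 4L, c(32, 32)))
    lossfun <- function() {
      fwd <- nn_forward(m, x, train = TRUE, want_cache = TRUE)
      bl <- fetalhc:::batch_loss_grads(m, fwd, tg, c(), TRUE, TRUE, TRUE,
                                       TRUE)
      list(L = bl$breakdown$total, fwd = fwd, dz = bl$dz)
    }
    r <- lossfun()
    grads <- nn_backward(m, r$fwd, r$dz)
    nms <- sample(names(grads), 10)
    for (nm in nms) {
      i <- sample(length(m$params[[nm]]), 1)
      old <- m$params[[nm]][i]
      h <- 1e-5 * max(1, abs(old))
      m$params[[nm]][i] <- old + h; Lp <- lossfun()$L
      m$params[[nm]][i] <- old - h; Lm <- lossfun()$L
      m$params[[nm]][i] <- old
      gnum <- (Lp - Lm) / (2 * h)
      expect_equal(grads[[nm]][i], gnum,
                   tolerance = 1e-3 * max(1, abs(gnum)),
                   label = sprintf("analytic grad of %s (mhsa=%s)", nm, mh))
    }
  }
})

test_that("a tiny model overfits a fixed batch (loss decreases)", {
  set.seed(1)
  m <- build_model(micro_cfg(FALSE), seed = 10, quiet = TRUE)
  pc <- phantom_config(image_size = c(32, 32), semi_axis_range = c(6, 10),
                       ring_thickness = 2)
  samples <- lapply(1:4, function(i) generate_phantom(pc, i))
  x <- fetalhc:::stack_images(samples)
  tg <- lapply(samples, function(sm)
    encode_targets(sm$annotation, 4L, c(32, 32)))
  state <- new.env(parent = emptyenv())
  losses <- numeric(50)
  for (it in 1:50)
    losses[it] <- fetalhc:::train_step(m, x, tg, state, lr = 0.005)$total
  expect_lt(mean(tail(losses, 5)), 0.5 * mean(head(losses, 5)))
})

test_that("checkpoints round-trip and refuse mismatched configurations", {
  m <- build_model(micro_cfg(FALSE), seed = 4, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path, expect_cfg = micro_cfg(FALSE))
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(nn_forward(m, x)$out, nn_forward(m2, x)$out)
  expect_error(load_checkpoint(path, expect_cfg = micro_cfg(TRUE)),
               "does not match")
})
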