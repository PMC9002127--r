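test_that("MAE and ME arithmetic and sign convention", {
  r <- mae_me(c(100, 102), c(101, 101))
  expect_equal(r$mae, 1.0)
  expect_equal(r$me, 0.0)
  r <- mae_me(c(103), c(101))
  expect_equal(r$mae, 2.0)
  expect_equal(r$me, 2.0) # prediction minus ground truth
  r <- mae_me(c(5, 5), c(5, 5))
  expect_equal(c(r$mae, r$me), c(0, 0))
  expect_error(mae_me(1:3, 1:2), "length")
  # permutation invariance
  set.seed(2)
  p <- runif(20, 90, 110); g <- runif(20, 90, 110)
  i <- sample(20)
  expect_equal(mae_me(p, g)$mae, mae_me(p[i], g[i])$mae)
  expect_equal(mae_me(p, g)$me_sd, mae_me(p[i], g[i])$me_sd)
})

test_that("average precision on hand-checked configurations", {
  gt <- ellipse(50, 50, 20, 15, 30)
  close_e <- ellipse(51, 50, 20, 15, 30)
  far_e <- ellipse(120, 120, 20, 15, 30)
  # one TP with high overlap
  expect_equal(average_precision(list(list(list(ellipse = close_e,
                                                score = 0.9))),
                                 list(list(gt))), 1.0)
  # overlap below threshold
  expect_equal(average_precision(list(list(list(ellipse = far_e,
                                                score = 0.9))),
                                 list(list(gt))), 0.0)
  # FP at 0.9 then TP at 0.8: PR = (0,0), (1, 0.5) -> AP 0.5
  expect_equal(average_precision(
    list(list(list(ellipse = far_e, score = 0.9),
              list(ellipse = close_e, score = 0.8))),
    list(list(gt))), 0.5)
  expect_error(average_precision(list(list()), list(list())), "no ground")
})

test_that("greedy AP equals the exhaustive-assignment oracle", {
  set.seed(99)
  for (case in 1:20) {
    n_img <- sample(1:2, 1)
    gts <- lapply(seq_len(n_img), function(i) {
      k <- sample(0:2, 1)
      lapply(seq_len(k), function(j)
        ellipse(runif(1, 30, 70), runif(1, 30, 70), runif(1, 10, 16),
                runif(1, 7, 10), runif(1, 0, 180)))
    })
    if (sum(lengths(gts)) == 0) gts[[1]] <- list(ellipse(50, 50, 12, 9, 10))
    preds <- lapply(gts, function(g) {
      dets <- list()
      for (e in g) {
        if (runif(1) < 0.8)
          dets[[length(dets) + 1]] <- list(
            ellipse = ellipse(e$cx + rnorm(1, 0, 2), e$cy + rnorm(1, 0, 2),
                              e$a * runif(1, 0.9, 1.1),
                              min(e$a, e$b * runif(1, 0.9, 1.1)),
                              e$theta), score = runif(1))
      }
      if (runif(1) < 0.4)
        dets[[length(dets) + 1]] <- list(
          ellipse = ellipse(runif(1, 20, 80), runif(1, 20, 80), 8, 6,
                            runif(1, 0, 180)), score = runif(1))
      dets
    })
    if (sum(lengths(preds)) > 5) next
    expect_equal(average_precision(preds, gts),
                 brute_force_ap(preds, gts), tolerance = 1e-10)
  }
})

test_that("Bland-Altman bias and limits of agreement", {
  r <- bland_altman(c(100, 100, 100), c(100, 100, 100))
  expect_equal(c(r$mean_diff, r$loa_low, r$loa_high), c(0, 0, 0))
  r <- bland_altman(c(101, 99, 102, 98), c(100, 100, 100, 100))
  expect_equal(r$mean_diff, 0)
  expect_equal(r$loa_high, 1.96 * sqrt(10 / 3), tolerance = 1e-9)
  expect_equal(r$loa_low, -1.96 * sqrt(10 / 3), tolerance = 1e-9)
  # translation equivariance of the bias
  p <- c(98, 102, 100.5); g <- c(99, 101, 100)
  expect_equal(bland_altman(p + 3, g)$mean_diff,
               bland_altman(p, g)$mean_diff + 3)
  expect_error(bland_altman(1, 1), "at least two")
})

test_that("evaluation report composes metrics over a prediction table", {
  cfg <- phantom_config(image_size = c(64, 64), semi_axis_range = c(10, 16))
  samples <- generate_samples(4, 1, cfg, seed = 55)
  anns <- lapply(samples, `[[`, "annotation")
  # oracle predictions: copy the ground truth
  pred_df <- do.call(rbind, lapply(anns, function(an) {
    if (an$is_negative)
      data.frame(image_id = an$image_id, cx = NA, cy = NA, a = NA, b = NA,
                 theta_deg = NA, score = NA, hc_mm = NA)
    else
      data.frame(image_id = an$image_id, cx = an$ellipse$cx,
                 cy = an$ellipse$cy, a = an$ellipse$a, b = an$ellipse$b,
                 theta_deg = an$ellipse$theta, score = 0.99,
                 hc_mm = head_circumference(an$ellipse$a * an$pixel_size_mm,
                                            an$ellipse$b * an$pixel_size_mm))
  }))
  rep <- evaluate_predictions(pred_df, anns)
  expect_equal(rep$mae_mm, 0)
  expect_equal(rep$me_mm, 0)
  expect_equal(rep$ap, 1.0)
  expect_equal(rep$bland_altman$mean_diff, 0)
})
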