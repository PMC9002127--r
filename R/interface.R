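# Tool surface: dataset-on-disk helpers, prediction/evaluation over
# directories, a YAML-compatible config file, and the CLI dispatcher behind
# inst/cli/fetalhc.

#' Load a phantom dataset directory into memory
#'
#' Reads `annotations.csv` plus the PNGs written by [generate_dataset()].
#'
#' @param dir Dataset directory.
#' @return List of `"phantom_sample"`-shaped objects.
#' @export
load_dataset <- function(dir) {
  anns <- read_annotations(file.path(dir, "annotations.csv"))
  lapply(anns, function(an) {
    structure(list(image = read_image(file.path(dir, paste0(an$image_id, ".png"))),
                   annotation = an, seed = NA_integer_),
              class = "phantom_sample")
  })
}

#' Predict ellipses and HC for a set of images
#'
#' @param model A trained `"fh_model"`.
#' @param samples List of samples (`image` + `annotation` with the pixel
#'   size), e.g. from [load_dataset()] or [generate_samples()].
#' @param threshold Score threshold (default 0.3).
#' @return Data frame in the predictions dialect:
#'   `image_id, cx, cy, a, b, theta_deg, score, hc_mm` (NA rows for images
#'   with no detection).
#' @export
predict_samples <- function(model, samples, threshold = 0.3) {
  rows <- lapply(samples, function(sm) {
    p <- predict_hc(sm$image, model, sm$annotation$pixel_size_mm, threshold)
    if (p$detected)
      data.frame(image_id = sm$annotation$image_id, cx = p$ellipse$cx,
                 cy = p$ellipse$cy, a = p$ellipse$a, b = p$ellipse$b,
                 theta_deg = p$ellipse$theta, score = p$score,
                 hc_mm = p$hc_mm)
    else
      data.frame(image_id = sm$annotation$image_id, cx = NA_real_,
                 cy = NA_real_, a = NA_real_, b = NA_real_,
                 theta_deg = NA_real_, score = NA_real_, hc_mm = NA_real_)
  })
  do.call(rbind, rows)
}

#' Evaluate a predictions table against a ground-truth annotation table
#'
#' Joins on `image_id`; negative ground-truth rows contribute no GT ellipse,
#' undetected predictions contribute no detection. HC errors are computed on
#' the subset with both a detection and a positive ground truth.
#'
#' @param pred_df Data frame from [predict_samples()] (or its CSV).
#' @param gt_anns List of [annotation()] objects (or annotation CSV path).
#' @param iou_threshold AP matching threshold.
#' @return An [eval_report()].
#' @export
evaluate_predictions <- function(pred_df, gt_anns, iou_threshold = 0.5) {
  if (is.character(gt_anns)) gt_anns <- read_annotations(gt_anns)
  if (is.character(pred_df)) pred_df <- utils::read.csv(pred_df)
  gt_by_id <- stats::setNames(gt_anns,
                              vapply(gt_anns, `[[`, character(1), "image_id"))
  preds <- list(); gts <- list(); pred_hc <- c(); gt_hc <- c()
  for (i in seq_len(nrow(pred_df))) {
    r <- pred_df[i, ]
    an <- gt_by_id[[as.character(r$image_id)]]
    if (is.null(an)) stop("evaluate_predictions: no ground truth for ",
                          r$image_id)
    gts[[i]] <- if (an$is_negative) list() else list(an$ellipse)
    preds[[i]] <- if (is.na(r$score)) list() else
      list(list(ellipse = ellipse(r$cx, r$cy, r$a, r$b, r$theta_deg),
                score = r$score))
    if (!is.na(r$score) && !an$is_negative) {
      pred_hc <- c(pred_hc, r$hc_mm)
      gt_hc <- c(gt_hc, head_circumference(
        an$ellipse$a * an$pixel_size_mm, an$ellipse$b * an$pixel_size_mm))
    }
  }
  eval_report(preds, gts, pred_hc, gt_hc, iou_threshold)
}

#' Read a key-value configuration file (YAML)
#'
#' Keys mirror the CLI flags (`preset`, `epochs`, `lr`, `momentum`,
#' `batch_size`, `use_mhsa`, `use_ssr`, `use_kld`, `include_axes`,
#' `dropout`, `threshold`, `seed`, ...). CLI flags override file values.
#'
#' @param path YAML file.
#' @return Named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

cli_args_to_list <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("cli: unexpected argument '", a, "'")
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      out[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  out
}

cli_num <- function(x, default) if (is.null(x)) default else as.numeric(x)
cli_int <- function(x, default) if (is.null(x)) default else as.integer(x)
cli_chr <- function(x, default = NULL) if (is.null(x)) default else as.character(x)
cli_flag <- function(x) isTRUE(x) || identical(x, "true") || identical(x, "TRUE")

#' Command-line entry point
#'
#' Dispatches the subcommands behind the `fetalhc` script
#' (`inst/cli/fetalhc`): `synth` (generate a phantom dataset), `train`
#' (optimise the detector), `predict` (images to predictions CSV with HC),
#' `eval` (predictions + ground truth to a JSON report). Every run echoes
#' its configuration and seed; `train` logs the per-epoch loss breakdown.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly (0 on success).
#' @export
fh_cli <- function(args) {
  if (length(args) == 0) {
    message("usage: fetalhc <synth|train|predict|eval> [--flag value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opt <- tryCatch(cli_args_to_list(args[-1]), error = function(e) e)
  if (inherits(opt, "error")) { message(conditionMessage(opt)); return(invisible(1L)) }
  if (!is.null(opt$config)) {
    file_opt <- read_config(opt$config)
    for (k in names(file_opt)) if (is.null(opt[[k]])) opt[[k]] <- file_opt[[k]]
  }
  seed <- cli_int(opt$seed, 1L)
  message("fetalhc ", cmd, " | seed=", seed, " | ",
          paste(names(opt), unlist(lapply(opt, format)), sep = "=",
                collapse = " "))
  status <- tryCatch({
    switch(cmd,
      synth = {
        out <- cli_chr(opt$out, "phantoms")
        size <- cli_int(opt$image_size, 96L)
        cfg <- phantom_config(image_size = c(size, size),
                              gap_fraction = cli_num(opt$gap_fraction, 0.2),
                              speckle = cli_num(opt$speckle, 0.3))
        generate_dataset(cli_int(opt$n_pos, 20L), cli_int(opt$n_neg, 0L),
                         cfg, out, seed = seed)
        message("wrote dataset to ", out)
        0L
      },
      train = {
        data_dir <- cli_chr(opt$data)
        if (is.null(data_dir)) stop("train: --data is required")
        samples <- load_dataset(data_dir)
        size <- dim(samples[[1]]$image)
        cfg <- preset_config(cli_chr(opt$preset, "tiny"),
                             input_size = c(size[1], size[2]))
        fit <- train_model(samples, cfg = cfg,
                           epochs = cli_int(opt$epochs, 5L),
                           batch_size = cli_int(opt$batch_size, 4L),
                           lr = cli_num(opt$lr, 0.005),
                           momentum = cli_num(opt$momentum, 0.9),
                           use_ssr = !cli_flag(opt$no_ssr),
                           use_kld = !cli_flag(opt$no_kld),
                           seed = seed)
        ckpt <- cli_chr(opt$out, "model.rds")
        save_checkpoint(fit$model, ckpt)
        message("checkpoint written to ", ckpt)
        0L
      },
      predict = {
        model <- load_checkpoint(cli_chr(opt$checkpoint, "model.rds"))
        samples <- load_dataset(cli_chr(opt$data))
        df <- predict_samples(model, samples,
                              threshold = cli_num(opt$threshold, 0.3))
        out <- cli_chr(opt$out, "predictions.csv")
        utils::write.csv(df, out, row.names = FALSE)
        message("predictions written to ", out)
        0L
      },
      eval = {
        pred_path <- cli_chr(opt$pred, "predictions.csv")
        gt_path <- cli_chr(opt$gt, "annotations.csv")
        rep <- evaluate_predictions(pred_path, gt_path,
                                    iou_threshold = cli_num(opt$iou, 0.5))
        print(rep)
        if (!is.null(opt$per_image)) {
          pd <- utils::read.csv(pred_path)
          gt_anns <- read_annotations(gt_path)
          gt_hc <- vapply(gt_anns, function(an)
            if (an$is_negative) NA_real_ else
              head_circumference(an$ellipse$a * an$pixel_size_mm,
                                 an$ellipse$b * an$pixel_size_mm),
            numeric(1))
          names(gt_hc) <- vapply(gt_anns, `[[`, character(1), "image_id")
          per <- data.frame(image_id = pd$image_id,
                            pred_hc_mm = pd$hc_mm,
                            gt_hc_mm = unname(gt_hc[as.character(pd$image_id)]))
          per$diff_mm <- per$pred_hc_mm - per$gt_hc_mm
          per$mean_mm <- (per$pred_hc_mm + per$gt_hc_mm) / 2
          utils::write.csv(per, opt$per_image, row.names = FALSE)
          message("per-image errors written to ", opt$per_image)
        }
        if (!is.null(opt$out))
          jsonlite::write_json(
            list(mae_mm = rep$mae_mm, mae_sd_mm = rep$mae_sd_mm,
                 me_mm = rep$me_mm, me_sd_mm = rep$me_sd_mm, ap = rep$ap,
                 bland_altman = rep$bland_altman[c("mean_diff", "loa_low",
                                                   "loa_high")],
                 n = rep$n),
            opt$out, auto_unbox = TRUE, digits = NA)
        0L
      },
      {
        message("fetalhc: unknown command '", cmd, "'")
        1L
      })
  }, error = function(e) {
    message("fetalhc ", cmd, " failed: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
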