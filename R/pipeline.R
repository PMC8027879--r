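# End-to-end orchestration: simulate -> train -> segment -> morph ->
# evaluate, with every stage seeded and logged, outputs written under a run
# directory.

#' Default pipeline configuration
#'
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "train", "segment", "morph", "evaluate")`.
#' @param n_train,n_test Phantom counts for the simulate stage.
#' @param phantom A [phantom_config()].
#' @param train A [train_config()].
#' @param min_area,length_mode Morphometry options.
#' @param seed Global seed; stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(stages = c("simulate", "train", "segment", "morph",
                                  "evaluate"),
                       n_train = 30L, n_test = 10L,
                       phantom = phantom_config(),
                       train = train_config(),
                       min_area = 10L, length_mode = "path", seed = 1L) {
  structure(list(stages = stages, n_train = as.integer(n_train),
                 n_test = as.integer(n_test), phantom = phantom,
                 train = train, min_area = as.integer(min_area),
                 length_mode = length_mode, seed = as.integer(seed)),
            class = "run_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full phantom-to-report pipeline
#'
#' Executes the requested stages in order under `out_dir`: phantom
#' simulation (train and test sets), model training, segmentation of the
#' test images, morphometry of the predicted masks, and evaluation against
#' the ground-truth masks (per-image segmentation metrics plus Bland-Altman
#' agreement of the morphometric parameters). Each stage logs its seed and
#' elapsed time; identical config and seed give identical CSV outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisible list with the trained model, reports, and file paths.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf))
  yaml::write_yaml(lapply(unclass(config), function(x)
    if (is.list(x)) unclass(x) else x), file.path(out_dir, "config.yaml"))
  res <- list()
  stage_known <- c("simulate", "train", "segment", "morph", "evaluate")
  bad <- setdiff(config$stages, stage_known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tic <- function() proc.time()[["elapsed"]]

  if ("simulate" %in% config$stages) {
    t0 <- tic()
    res$train_set <- simulate_phantoms(config$phantom, config$n_train,
                                       seed = config$seed)
    res$test_set <- simulate_phantoms(config$phantom, config$n_test,
                                      seed = config$seed + config$n_train)
    log_line(logf, "[simulate] %d train + %d test phantoms, seed %d (%.1fs)",
             config$n_train, config$n_test, config$seed, tic() - t0)
  }
  if ("train" %in% config$stages) {
    if (is.null(res$train_set)) {
      stop("stage 'train' needs the simulate stage (no training inputs)",
           call. = FALSE)
    }
    t0 <- tic()
    model <- build_unet(config$train)
    model <- train_unet(model,
                        lapply(res$train_set, `[[`, "image"),
                        lapply(res$train_set, `[[`, "mask"))
    res$model <- model
    utils::write.csv(model$history, file.path(out_dir, "history.csv"),
                     row.names = FALSE)
    log_line(logf, "[train] %d epochs, final train loss %.4f (%.1fs)",
             config$train$epochs, utils::tail(model$history$train_loss, 1),
             tic() - t0)
  }
  if ("segment" %in% config$stages) {
    if (is.null(res$model)) stop("stage 'segment' needs a trained model",
                                 call. = FALSE)
    t0 <- tic()
    res$probs <- lapply(res$test_set, function(s) predict(res$model, s$image))
    res$pred_masks <- lapply(res$probs, binarize,
                             threshold = config$train$binarize_threshold)
    per_img <- (tic() - t0) / length(res$test_set)
    log_line(logf, "[segment] %d images, %.2fs/image", length(res$probs),
             per_img)
  }
  if ("morph" %in% config$stages) {
    masks <- if (!is.null(res$pred_masks)) res$pred_masks
             else lapply(res$test_set, `[[`, "mask")
    t0 <- tic()
    res$morph <- lapply(masks, analyze_mask, min_area = config$min_area,
                        length_mode = config$length_mode)
    rows <- lapply(seq_along(res$morph), function(i) {
      m <- res$morph[[i]]
      data.frame(image = i, gland_count = m$gland_count,
                 mean_length = m$mean_length, mean_width = m$mean_width,
                 mean_tortuosity = m$mean_tortuosity)
    })
    morph_df <- do.call(rbind, rows)
    utils::write.csv(morph_df, file.path(out_dir, "morphometry.csv"),
                     row.names = FALSE)
    log_line(logf, "[morph] %d masks (%.1fs)", length(masks), tic() - t0)
  }
  if ("evaluate" %in% config$stages) {
    if (is.null(res$pred_masks)) stop("stage 'evaluate' needs segment outputs",
                                      call. = FALSE)
    if (is.null(res$morph)) stop("stage 'evaluate' needs morph outputs",
                                 call. = FALSE)
    t0 <- tic()
    gt <- lapply(res$test_set, `[[`, "mask")
    seg_rows <- lapply(seq_along(gt), function(i) {
      cc <- confusion_counts(res$pred_masks[[i]], gt[[i]])
      prf <- precision_recall_f1(cc)
      data.frame(image = i, precision = prf$precision, recall = prf$recall,
                 f1 = prf$f1,
                 dice = dice_coefficient(res$pred_masks[[i]], gt[[i]]),
                 auc = roc_auc(res$probs[[i]], gt[[i]]))
    })
    seg_df <- do.call(rbind, seg_rows)
    utils::write.csv(seg_df, file.path(out_dir, "segmentation_metrics.csv"),
                     row.names = FALSE)
    gt_morph <- lapply(gt, analyze_mask, min_area = config$min_area,
                       length_mode = config$length_mode)
    ba_rows <- list()
    for (par in c("gland_count", "mean_length", "mean_width",
                  "mean_tortuosity")) {
      man <- vapply(gt_morph, function(m) as.numeric(m[[par]]), 0)
      aut <- vapply(res$morph, function(m) as.numeric(m[[par]]), 0)
      ok <- is.finite(man) & is.finite(aut)
      if (sum(ok) >= 3) {
        ba <- bland_altman(man[ok], aut[ok])
        ba_rows[[par]] <- data.frame(
          parameter = par, mean_diff = ba$mean_diff, sd_diff = ba$sd_diff,
          loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
          fraction_within_loa = ba$fraction_within_loa,
          p_paired_t = ba$p_value_paired_t)
      }
    }
    res$bland_altman <- do.call(rbind, ba_rows)
    utils::write.csv(res$bland_altman,
                     file.path(out_dir, "bland_altman.csv"),
                     row.names = FALSE)
    log_line(logf, "[evaluate] mean dice %.3f (%.1fs)",
             mean(seg_df$dice), tic() - t0)
  }
  invisible(res)
}
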