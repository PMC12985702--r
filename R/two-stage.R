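#' Run the full two-stage training experiment on synthetic scenes
#'
#' Reproduces the pipeline's central behaviour at the scale given by
#' `config`: (1) a base model is trained on HSV weak labels of mixed scenes
#' (plumes plus red distractors) and scored against held-out weak labels;
#' (2) the base model is fine-tuned on a curated set whose distractor-only
#' images carry zero masks, and the change in false-positive area on
#' distractor-only scenes and in bleeding-scene Dice is measured against the
#' base model. All scene generation, splitting, training and evaluation
#' randomness derives from `seed`.
#'
#' @param seed Master seed.
#' @param config A [run_config()]; defaults to the `"test"` profile.
#' @param verbose Print per-epoch training lines.
#' @return List with `base_dice_holdout` (mean Dice of the base model against
#'   held-out weak labels), `fp_area_base` / `fp_area_finetuned` (mean
#'   predicted-positive pixels on distractor-only scenes),
#'   `fp_reduction` (relative drop), `bleeding_dice_base` /
#'   `bleeding_dice_finetuned` and `bleeding_dice_delta` (fine-tuned minus
#'   base, against truth bleeding masks), plus both checkpoints.
#' @export
two_stage_experiment <- function(seed = 1L, config = run_config("test"),
                                 verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  cfg <- config
  cfg$seed <- as.integer(seed)
  with_local_seed(cfg$seed, {
    n <- cfg$n_base_scenes
    fracs <- runif(n, 0.05, 0.45)
    srcs <- sprintf("vid%02d", rep(seq_len(cfg$n_sources), length.out = n))
    base_scenes <- .make_scene_set(cfg, 1L, n, fracs, TRUE, TRUE, srcs)
    cur_b_scenes <- .make_scene_set(cfg, 2L, cfg$n_curated_bleeding,
                                    runif(cfg$n_curated_bleeding, 0.1, 0.4),
                                    TRUE, TRUE,
                                    sprintf("cur%02d", seq_len(cfg$n_curated_bleeding)))
    cur_d_scenes <- .make_scene_set(cfg, 3L, cfg$n_curated_distractor, 0,
                                    TRUE, TRUE,
                                    sprintf("cur%02d", 50L + seq_len(cfg$n_curated_distractor)))
    mon_scenes <- .make_scene_set(cfg, 4L, cfg$n_monitor,
                                  runif(cfg$n_monitor, 0.05, 0.4), TRUE, TRUE,
                                  sprintf("mon%02d", seq_len(cfg$n_monitor)))
    eval_b <- .make_scene_set(cfg, 5L, cfg$n_eval_bleeding,
                              runif(cfg$n_eval_bleeding, 0.1, 0.45), TRUE, TRUE,
                              sprintf("ev%02d", seq_len(cfg$n_eval_bleeding)))
    eval_d <- .make_scene_set(cfg, 6L, cfg$n_eval_distractor, 0, TRUE, TRUE,
                              sprintf("ev%02d", 50L + seq_len(cfg$n_eval_distractor)))

    pairs <- lapply(base_scenes, function(sc) {
      wl <- weak_label(sc$image)
      labeled_pair(sc$image, wl$mask, wl$ratio, attr(sc, "source_id"))
    })
    pairs <- filter_pairs(pairs, cfg$min_ratio)
    sp <- split_by_source(pairs, cfg$val_frac, seed = cfg$seed)

    model <- build_model(model_spec(cfg$image_size, cfg$widths), seed = cfg$seed)
    base_ckpt <- train_base(model, sp$train, sp$val,
                            train_config(learning_rate = cfg$learning_rate,
                                         batch_size = cfg$batch_size,
                                         patience = cfg$patience_base,
                                         max_epochs = cfg$max_epochs_base,
                                         seed = cfg$seed), verbose = verbose)
    base_dice <- mean(vapply(sp$val, function(p)
      dice_iou(suppressWarnings(predict_mask(base_ckpt, p$image)),
               p$mask)$dice, numeric(1)))

    curated <- c(
      lapply(cur_b_scenes, function(sc)
        curated_sample(sc$image, sc$bleeding_mask, "bleeding_red_mask",
                       source_id = attr(sc, "source_id"))),
      lapply(cur_d_scenes, function(sc)
        curated_sample(sc$image, matrix(FALSE, nrow(sc$image), ncol(sc$image)),
                       "zero_mask", source_id = attr(sc, "source_id"))))
    monitor <- lapply(mon_scenes, function(sc)
      list(image = sc$image, mask = sc$bleeding_mask,
           source_id = attr(sc, "source_id")))
    ft_ckpt <- finetune(base_ckpt, curated, monitor,
                        train_config(learning_rate = cfg$learning_rate,
                                     batch_size = cfg$batch_size,
                                     patience = cfg$patience_finetune,
                                     max_epochs = cfg$max_epochs_finetune,
                                     monitor = "dice",
                                     augment = augment_spec(seed = cfg$seed),
                                     seed = cfg$seed), verbose = verbose)

    fp_area <- function(m) mean(vapply(eval_d, function(sc)
      sum(suppressWarnings(predict_mask(m, sc$image))), numeric(1)))
    bdice <- function(m) mean(vapply(eval_b, function(sc)
      dice_iou(suppressWarnings(predict_mask(m, sc$image)),
               sc$bleeding_mask)$dice, numeric(1)))
    fpb <- fp_area(base_ckpt); fpf <- fp_area(ft_ckpt)
    db <- bdice(base_ckpt); df <- bdice(ft_ckpt)
    list(base_dice_holdout = base_dice,
         fp_area_base = fpb, fp_area_finetuned = fpf,
         fp_reduction = if (fpb > 0) 1 - fpf / fpb else NA_real_,
         bleeding_dice_base = db, bleeding_dice_finetuned = df,
         bleeding_dice_delta = df - db,
         base_ckpt = base_ckpt, finetuned_ckpt = ft_ckpt,
         eval_bleeding = eval_b, eval_distractor = eval_d)
  })
}
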