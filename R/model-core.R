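#' Segmentation model specification
#'
#' A compact nested-skip convolutional encoder--decoder producing a 1-channel
#' logit map at input resolution. `widths` gives the channel counts of the
#' two encoder levels and the bottleneck. The `"paper"` profile uses 512 px
#' inputs and full widths; the `"test"` profile (128 px, widths divided by 4)
#' is a first-class configuration so CPU-scale experiments and tests run in
#' minutes with the same formulas.
#'
#' @param input_size Input side length in pixels; must be divisible by 4.
#' @param widths Integer vector `c(c0, c1, c2)` of channel widths.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(input_size = 512L, widths = c(32L, 64L, 128L)) {
  if (input_size %% 4 != 0) stop("input_size must be divisible by 4", call. = FALSE)
  stopifnot(length(widths) == 3, all(widths >= 1))
  structure(list(input_size = as.integer(input_size),
                 widths = as.integer(widths)), class = "model_spec")
}

#' @rdname model_spec
#' @param profile `"paper"` or `"test"`.
#' @export
default_model_spec <- function(profile = c("paper", "test")) {
  profile <- match.arg(profile)
  if (profile == "paper") model_spec(512L, c(32L, 64L, 128L))
  else model_spec(128L, c(4L, 8L, 16L))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size Images per gradient step (default 4).
#' @param patience Early-stopping patience in epochs: 20 for base training on
#'   the validation loss, 10 for fine-tuning on the monitored Dice.
#' @param max_epochs Hard epoch cap.
#' @param improvement_epsilon Minimum absolute change that counts as an
#'   improvement of the monitored quantity.
#' @param monitor `"loss"` (minimised; base training) or `"dice"` (maximised;
#'   fine-tuning).
#' @param augment Optional [augment_spec()] applied to training samples.
#' @param seed Master seed covering init, shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         patience = 20L, max_epochs = 100L,
                         improvement_epsilon = 1e-4,
                         monitor = c("loss", "dice"), augment = NULL,
                         seed = 1L) {
  stopifnot(learning_rate > 0, patience >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 improvement_epsilon = improvement_epsilon,
                 monitor = match.arg(monitor), augment = augment,
                 seed = as.integer(seed)), class = "train_config")
}

#' Build a randomly initialised segmentation model
#'
#' He-normal initialisation for conv weights, zero biases; no pretrained
#' weights are used anywhere. Identical spec and seed give identical weights.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return An object of class `endo_model`.
#' @export
build_model <- function(spec = default_model_spec("paper"), seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  c0 <- spec$widths[1]; c1 <- spec$widths[2]; c2 <- spec$widths[3]
  he <- function(fan_in, n_out)
    matrix(rnorm(fan_in * n_out, 0, sqrt(2 / fan_in)), fan_in, n_out)
  weights <- with_local_seed(seed, list(
    e0_W = he(9 * 3, c0),            e0_b = numeric(c0),
    e1_W = he(9 * c0, c1),           e1_b = numeric(c1),
    bt_W = he(9 * c1, c2),           bt_b = numeric(c2),
    d1_W = he(9 * (c1 + c2), c1),    d1_b = numeric(c1),
    x01_W = he(9 * (c0 + c1), c0),   x01_b = numeric(c0),
    d0_W = he(9 * (2 * c0 + c1), c0), d0_b = numeric(c0),
    hd_W = matrix(rnorm(c0, 0, sqrt(1 / c0)), c0, 1), hd_b = 0))
  structure(list(weights = weights, spec = spec, seed = as.integer(seed)),
            class = "endo_model")
}

#' Binary cross-entropy with logits
#'
#' Mean over pixels of `-(t * log(sigmoid(z)) + (1 - t) * log(1 - sigmoid(z)))`
#' evaluated in the numerically stable logit form
#' `max(z, 0) - z * t + log(1 + exp(-|z|))`.
#'
#' @param logits Numeric array of logits.
#' @param targets Binary array of the same shape.
#' @return Scalar loss.
#' @export
bce_logit_loss <- function(logits, targets) {
  if (!all(dim(logits) == dim(targets)))
    stop("logits and targets must have the same shape", call. = FALSE)
  if (!all(targets %in% c(0, 1)))
    stop("targets must be binary", call. = FALSE)
  t <- as.numeric(targets)
  z <- as.numeric(logits)
  mean(pmax(z, 0) - z * t + log1p(exp(-abs(z))))
}

.model_weights <- function(m) {
  if (inherits(m, "endo_checkpoint")) m$weights
  else if (inherits(m, "endo_model")) m$weights
  else stop("expected an endo_model or endo_checkpoint", call. = FALSE)
}

#' Raw logit map for one image
#'
#' @param model An `endo_model` or `endo_checkpoint`.
#' @param image_norm Standardised H x W x 3 array (see [normalize_image()]).
#' @return H x W numeric matrix of logits.
#' @export
predict_logits <- function(model, image_norm) {
  .nn_forward_cpp(.model_weights(model), image_norm)
}

#' Predicted bleeding probability map
#'
#' @inheritParams predict_mask
#' @return H x W matrix of probabilities `sigmoid(logit)`.
#' @export
predict_prob <- function(model, image, norm = normalization_spec()) {
  image <- .auto_normalize(image, norm)
  plogis(predict_logits(model, image))
}

.auto_normalize <- function(image, norm) {
  if (max(abs(image)) > 1.5 && min(image) >= 0) {
    warning("input looks like an 8-bit image; normalizing automatically",
            call. = FALSE)
    image <- normalize_image(image, norm)
  }
  image
}

#' Predict a binary bleeding mask
#'
#' Probabilities are the sigmoid of the logits; a pixel is positive iff its
#' probability strictly exceeds `threshold` (a logit of exactly 0 is negative
#' at the default 0.5).
#'
#' @param model An `endo_model` or `endo_checkpoint`.
#' @param image Standardised array, or an 8-bit image (auto-normalised with a
#'   warning).
#' @param threshold Probability threshold (default 0.5).
#' @param norm A [normalization_spec()] used for auto-normalisation.
#' @return Logical H x W matrix.
#' @export
predict_mask <- function(model, image, threshold = 0.5,
                         norm = normalization_spec()) {
  predict_prob(model, image, norm) > threshold
}

# ---- Adam ----------------------------------------------------------------

.adam_init <- function(weights) {
  zero <- lapply(weights, function(w) w * 0)
  list(m = zero, v = zero, t = 0L)
}

.adam_step <- function(weights, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / bc1
    vh <- state$v[[nm]] / bc2
    weights[[nm]] <- weights[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(weights = weights, state = state)
}

.sum_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(a)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

.scale_grads <- function(g, s) lapply(g, function(x) x * s)

# Mean loss of `weights` over a list of (normalized image, target) pairs.
.eval_loss <- function(weights, xs, ts) {
  mean(vapply(seq_along(xs), function(i) {
    z <- .nn_forward_cpp(weights, xs[[i]])
    bce_logit_loss(z, ts[[i]])
  }, numeric(1)))
}

# Early-stopping bookkeeping: stop after max(patience, 1) consecutive
# non-improving epochs (improvement = change > epsilon in the right direction).
.improved <- function(value, best, eps, maximize) {
  if (is.null(best)) return(TRUE)
  if (maximize) value > best + eps else value < best - eps
}

#' Train the base model on weak labels
#'
#' Minimises BCE-with-logits with Adam, shuffled mini-batches, and early
#' stopping on the validation loss: training halts after `patience`
#' consecutive epochs without an improvement greater than
#' `improvement_epsilon`, and the checkpoint of the best validation epoch is
#' returned. A non-finite loss aborts with a diagnostic.
#'
#' @param model An `endo_model` from [build_model()].
#' @param train_pairs,val_pairs Lists of `list(image =, mask =)` with 8-bit
#'   images and binary masks (weak labels).
#' @param cfg A [train_config()] with `monitor = "loss"`.
#' @param norm A [normalization_spec()].
#' @param verbose Print a per-epoch line.
#' @return An `endo_checkpoint`: best weights, best epoch, monitored metric,
#'   per-epoch `history` data frame, config and its hash.
#' @export
train_base <- function(model, train_pairs, val_pairs, cfg = train_config(),
                       norm = normalization_spec(), verbose = FALSE) {
  stopifnot(inherits(model, "endo_model"), length(train_pairs) > 0,
            length(val_pairs) > 0)
  xs <- lapply(train_pairs, function(p) normalize_image(p$image, norm))
  ts <- lapply(train_pairs, function(p) as_mask(p$mask) * 1)
  vxs <- lapply(val_pairs, function(p) normalize_image(p$image, norm))
  vts <- lapply(val_pairs, function(p) as_mask(p$mask) * 1)
  .train_loop(model$weights, xs, ts, cfg,
              eval_fun = function(w) .eval_loss(w, vxs, vts),
              maximize = FALSE, metric_name = "val_loss", verbose = verbose)
}

.train_loop <- function(weights, xs, ts, cfg, eval_fun, maximize,
                        metric_name, verbose = FALSE, aug_images = NULL) {
  state <- .adam_init(weights)
  best <- NULL; best_weights <- weights; best_epoch <- 0L; bad <- 0L
  history <- NULL
  n <- length(xs)
  with_local_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gsum <- NULL; bloss <- 0
        for (i in idx) {
          xi <- xs[[i]]; ti <- ts[[i]]
          if (!is.null(cfg$augment)) {
            sp <- cfg$augment
            sp$seed <- sample.int(2^30, 1)  # fresh sub-seed, still under master
            img8 <- if (is.null(aug_images)) NULL else aug_images[[i]]
            if (!is.null(img8)) {
              a <- augment(img8, ti, sp)
              xi <- normalize_image(a$image)
              ti <- a$mask * 1
            }
          }
          g <- .nn_grad_cpp(weights, xi, ti)
          if (!is.finite(g$loss))
            stop("training diverged (non-finite loss) at epoch ", epoch,
                 call. = FALSE)
          bloss <- bloss + g$loss
          gsum <- .sum_grads(gsum, g$grads)
        }
        gsum <- .scale_grads(gsum, 1 / length(idx))
        upd <- .adam_step(weights, gsum, state, cfg$learning_rate)
        weights <- upd$weights; state <- upd$state
        ep_loss <- ep_loss + bloss
      }
      metric <- eval_fun(weights)
      if (.improved(metric, best, cfg$improvement_epsilon, maximize)) {
        best <- metric; best_weights <- weights; best_epoch <- epoch; bad <- 0L
      } else {
        bad <- bad + 1L
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = ep_loss / n, metric = metric,
        best_metric = best))
      if (verbose)
        message(sprintf("epoch %3d  train_loss %.4f  %s %.4f (best %.4f)",
                        epoch, ep_loss / n, metric_name, metric, best))
      if (bad >= max(cfg$patience, 1L)) break
    }
  })
  names(history)[3] <- metric_name
  structure(list(weights = best_weights, epoch = best_epoch, metric = best,
                 history = history, config = cfg,
                 config_hash = config_hash(cfg[setdiff(names(cfg), "augment")])),
            class = "endo_checkpoint")
}

#' Fine-tune on a curated set, monitored by Dice against reference masks
#'
#' Resumes from the base checkpoint's weights and trains on curated samples
#' (bleeding red masks plus all-negative zero masks for red distractors,
#' entering the loss unweighted). Early stopping maximises the mean Dice over
#' the monitoring set (IoU is logged alongside); training halts after
#' `patience` consecutive epochs without improvement and the best-Dice
#' checkpoint is returned. Curated and monitoring sources must be disjoint;
#' shared source ids are refused.
#'
#' @param base_ckpt An `endo_checkpoint` from [train_base()].
#' @param curated List of [curated_sample()] objects.
#' @param monitor_pairs List of `list(image =, mask =, source_id =)` reference
#'   pairs (ground-truth masks).
#' @param cfg A [train_config()] with `monitor = "dice"` (typically
#'   `patience = 10`).
#' @param norm A [normalization_spec()].
#' @param verbose Print a per-epoch line.
#' @return An `endo_checkpoint` whose `metric` is the best mean Dice;
#'   `history` also carries the mean IoU per epoch.
#' @export
finetune <- function(base_ckpt, curated, monitor_pairs,
                     cfg = train_config(patience = 10L, monitor = "dice"),
                     norm = normalization_spec(), verbose = FALSE) {
  stopifnot(inherits(base_ckpt, "endo_checkpoint"), length(curated) > 0,
            length(monitor_pairs) > 0)
  cur_src <- unique(vapply(curated, function(p) p$source_id, character(1)))
  mon_src <- unique(vapply(monitor_pairs,
                           function(p) p$source_id %||% "unknown", character(1)))
  shared <- intersect(cur_src, mon_src)
  if (length(shared))
    stop_endobleed(paste0("source leakage between curated and monitoring sets: ",
                          paste(shared, collapse = ", ")),
                   "endobleed_leakage")
  xs <- lapply(curated, function(p) normalize_image(p$image, norm))
  ts <- lapply(curated, function(p) as_mask(p$mask) * 1)
  aug_images <- lapply(curated, function(p) p$image)
  mxs <- lapply(monitor_pairs, function(p) normalize_image(p$image, norm))
  mts <- lapply(monitor_pairs, function(p) as_mask(p$mask))
  model0 <- structure(list(weights = base_ckpt$weights), class = "endo_model")
  eval_fun <- function(w) {
    wmod <- structure(list(weights = w), class = "endo_checkpoint")
    mean(vapply(seq_along(mxs), function(i) {
      pm <- .nn_forward_cpp(w, mxs[[i]])
      dice_iou(plogis(pm) > 0.5, mts[[i]])$dice
    }, numeric(1)))
  }
  .train_loop(base_ckpt$weights, xs, ts, cfg, eval_fun, maximize = TRUE,
              metric_name = "val_dice", verbose = verbose,
              aug_images = aug_images)
}

#' Save / load a checkpoint
#'
#' Reloading reproduces bit-identical predictions on a fixed input.
#'
#' @param ckpt An `endo_checkpoint`.
#' @param path File path.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "endo_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "endo_checkpoint"))
  ckpt
}
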