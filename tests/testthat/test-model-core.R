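test_that("model forward pass honours the shape contract and seeding", {
  spec <- model_spec(64L, c(2L, 4L, 8L))
  m1 <- build_model(spec, seed = 7)
  m2 <- build_model(spec, seed = 7)
  set.seed(1)
  x <- array(rnorm(64 * 64 * 3), dim = c(64, 64, 3))
  z1 <- predict_logits(m1, x)
  expect_equal(dim(z1), c(64, 64))
  expect_true(all(is.finite(z1)))
  expect_identical(z1, predict_logits(m2, x))
  m3 <- build_model(spec, seed = 8)
  expect_false(identical(z1, predict_logits(m3, x)))
  expect_error(model_spec(130L), "divisible by 4")
})

test_that("BCE-with-logits matches its closed form and the C++ path", {
  z0 <- matrix(0, 5, 5)
  expect_equal(bce_logit_loss(z0, matrix(1, 5, 5)), log(2))
  expect_equal(bce_logit_loss(z0, matrix(0, 5, 5)), log(2))
  t <- matrix(rbinom(25, 1, 0.5), 5, 5)
  sat <- ifelse(t == 1, 20, -20)
  expect_lt(bce_logit_loss(sat, t), 1e-8)
  expect_error(bce_logit_loss(z0, matrix(0.5, 5, 5)), "binary")
  # direct high-precision evaluation on random values
  set.seed(3)
  z <- matrix(rnorm(64, sd = 2), 8, 8)
  t <- matrix(rbinom(64, 1, 0.4), 8, 8)
  direct <- -mean(t * log(plogis(z)) + (1 - t) * log(1 - plogis(z)))
  expect_equal(bce_logit_loss(z, t), direct, tolerance = 1e-12)
  # the C++ training loss agrees with the R loss on the same logits
  m <- build_model(model_spec(16L, c(2L, 2L, 2L)), seed = 1)
  x <- array(rnorm(16 * 16 * 3), dim = c(16, 16, 3))
  tt <- matrix(rbinom(256, 1, 0.3), 16, 16)
  g <- endobleed:::.nn_grad_cpp(m$weights, x, tt)
  expect_equal(g$loss, bce_logit_loss(predict_logits(m, x), tt),
               tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  set.seed(10)
  m <- build_model(model_spec(12L, c(2L, 3L, 4L)), seed = 5)
  x <- array(rnorm(12 * 12 * 3), dim = c(12, 12, 3))
  t <- matrix(rbinom(144, 1, 0.4), 12, 12)
  g <- endobleed:::.nn_grad_cpp(m$weights, x, t)
  eps <- 1e-6
  for (nm in names(m$weights)) {
    w <- m$weights[[nm]]
    for (i in sample(length(w), min(3, length(w)))) {
      wp <- m$weights; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- m$weights; wm[[nm]][i] <- wm[[nm]][i] - eps
      fd <- (endobleed:::.nn_grad_cpp(wp, x, t)$loss -
               endobleed:::.nn_grad_cpp(wm, x, t)$loss) / (2 * eps)
      expect_equal(as.numeric(g$grads[[nm]])[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("mask prediction thresholds sigmoid probabilities strictly", {
  m <- build_model(model_spec(32L, c(2L, 2L, 2L)), seed = 2)
  img <- array(runif(32 * 32 * 3, -1, 1), dim = c(32, 32, 3))
  z <- predict_logits(m, img)
  expect_identical(predict_mask(m, img), plogis(z) > 0.5)
  # zero weights give logit 0 everywhere: probability 0.5 is NOT positive
  m0 <- m
  m0$weights <- lapply(m$weights, function(w) w * 0)
  expect_false(any(predict_mask(m0, img)))
  expect_true(all(predict_prob(m0, img) == 0.5))
  # 8-bit input is auto-normalized with a warning
  s <- tiny_scene(seed = 1, frac = 0.2, size = 64)
  expect_warning(predict_mask(m, s$image), "normalizing")
})

test_that("early stopping contracts hold on a flat metric stream", {
  xs <- lapply(1:2, function(i) array(rnorm(8 * 8 * 3), dim = c(8, 8, 3)))
  ts <- lapply(1:2, function(i) matrix(0, 8, 8))
  run <- function(patience, max_epochs = 50) {
    cfg <- train_config(learning_rate = 1e-12, patience = patience,
                        max_epochs = max_epochs, seed = 1)
    endobleed:::.train_loop(build_model(model_spec(8L, c(1L, 1L, 1L)),
                                        seed = 1)$weights,
                            xs, ts, cfg, eval_fun = function(w) 1,
                            maximize = FALSE, metric_name = "val_loss")
  }
  expect_equal(nrow(run(10)$history), 11)   # stop at epoch 11 of the stream
  expect_equal(nrow(run(0)$history), 2)     # first non-improving epoch stops
  expect_equal(run(10)$epoch, 1)
})

test_that("a single image can be overfit to its own weak label", {
  s <- tiny_scene(seed = 17, frac = 0.25, size = 64)
  wl <- weak_label(s$image)
  pair <- list(list(image = s$image, mask = wl$mask))
  model <- build_model(model_spec(64L, c(4L, 8L, 16L)), seed = 1)
  cfg <- train_config(learning_rate = 3e-3, batch_size = 1, patience = 60,
                      max_epochs = 60, seed = 1)
  ck <- train_base(model, pair, pair, cfg)
  d <- dice_iou(suppressWarnings(predict_mask(ck, s$image)), wl$mask)$dice
  expect_gte(d, 0.95)
  # best-so-far column of the loss log is non-increasing
  expect_true(all(diff(ck$history$best_metric) <= 1e-12))
})

test_that("checkpoints round-trip with bit-identical predictions", {
  m <- build_model(model_spec(32L, c(2L, 2L, 2L)), seed = 3)
  ck <- structure(list(weights = m$weights, epoch = 1L, metric = 0.5,
                       history = NULL, config = NULL, config_hash = "x"),
                  class = "endo_checkpoint")
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, f)
  ck2 <- load_checkpoint(f)
  img <- array(rnorm(32 * 32 * 3), dim = c(32, 32, 3))
  expect_identical(predict_logits(ck, img), predict_logits(ck2, img))
})

test_that("fine-tuning refuses shared sources between curated and monitor sets", {
  img <- tiny_scene(seed = 1, frac = 0.2, size = 64)$image
  mask <- matrix(FALSE, 64, 64); mask[10:12, 10:12] <- TRUE
  cur <- list(curated_sample(img, mask, "bleeding_red_mask", source_id = "v1"))
  mon <- list(list(image = img, mask = mask, source_id = "v1"))
  ck <- structure(list(weights = build_model(model_spec(64L, c(1L, 1L, 1L)),
                                             seed = 1)$weights),
                  class = "endo_checkpoint")
  expect_error(finetune(ck, cur, mon), class = "endobleed_leakage")
})
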