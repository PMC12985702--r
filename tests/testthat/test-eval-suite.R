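test_that("Dice and IoU follow their counting definitions", {
  m <- random_mask(10, seed = 1)
  expect_equal(dice_iou(m, m), list(dice = 1, iou = 1))
  a <- matrix(FALSE, 4, 4); a[1, 1:2] <- TRUE
  b <- matrix(FALSE, 4, 4); b[4, 3:4] <- TRUE
  expect_equal(dice_iou(a, b), list(dice = 0, iou = 0))
  # |A|=6, |B|=4, overlap 2 -> dice 0.4, iou 0.25
  a <- matrix(FALSE, 4, 4); a[1:6] <- TRUE
  b <- matrix(FALSE, 4, 4); b[5:8] <- TRUE
  sc <- dice_iou(a, b)
  expect_equal(sc, list(dice = 0.4, iou = 0.25))
  expect_equal(sc$dice, 2 * sc$iou / (1 + sc$iou))
  expect_error(dice_iou(a, matrix(FALSE, 3, 3)), "shape")
  # both empty: bookkeeping value 1
  expect_equal(dice_iou(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               list(dice = 1, iou = 1))
})

test_that("the Dice-IoU identity holds exactly over random mask pairs", {
  for (seed in 1:20) {
    a <- random_mask(12, p = 0.4, seed = seed)
    b <- random_mask(12, p = 0.4, seed = seed + 100)
    sc <- dice_iou(a, b)
    expect_equal(sc$dice, 2 * sc$iou / (1 + sc$iou), tolerance = 1e-12)
  }
})

test_that("image positivity requires a positive pixel inside the FOV", {
  fov <- matrix(FALSE, 6, 6); fov[2:5, 2:5] <- TRUE
  m <- matrix(FALSE, 6, 6)
  expect_false(image_class(m, fov))
  m[3, 3] <- TRUE
  expect_true(image_class(m, fov))
  m <- matrix(FALSE, 6, 6); m[1, 1] <- TRUE   # outside the FOV only
  expect_false(image_class(m, fov))
  expect_error(image_class(m, matrix(FALSE, 6, 6)), "empty field")
})

test_that("confusion tallies match a brute-force enumeration", {
  fov <- matrix(TRUE, 8, 8)
  perfect <- lapply(1:10, function(i) random_mask(8, p = 0.4, seed = i))
  names(perfect) <- sprintf("im%d", 1:10)
  gts <- lapply(perfect, function(m) list(r1 = m, r2 = m, r3 = m))
  cc <- confusion(perfect, gts, fov)
  expect_equal(cc$fp + cc$fn, 0L)
  expect_equal(cc$tp + cc$tn, 30L)
  empty <- lapply(perfect, function(m) matrix(FALSE, 8, 8))
  cc0 <- confusion(empty, gts, fov)
  expect_equal(cc0$tp + cc0$fp, 0L)
  # random fixture vs direct double loop
  set.seed(42)
  preds <- lapply(1:12, function(i) random_mask(8, p = 0.1, seed = 300 + i))
  names(preds) <- sprintf("im%d", 1:12)
  gts <- lapply(1:12, function(i) {
    out <- lapply(1:3, function(r) random_mask(8, p = 0.1, seed = 600 + 3 * i + r))
    names(out) <- c("r1", "r2", "r3"); out
  })
  names(gts) <- names(preds)
  cc <- confusion(preds, gts, fov)
  tp <- tn <- fp <- fn <- 0
  for (id in names(gts)) for (r in names(gts[[id]])) {
    p <- any(preds[[id]] & fov); g <- any(gts[[id]][[r]] & fov)
    tp <- tp + (p && g); tn <- tn + (!p && !g)
    fp <- fp + (p && !g); fn <- fn + (!p && g)
  }
  expect_equal(unclass(cc)[c("tp", "tn", "fp", "fn")],
               list(tp = tp, tn = tn, fp = fp, fn = fn),
               ignore_attr = TRUE)
  expect_error(confusion(preds[1:3], gts, fov), "misaligned")
})

test_that("detection metrics follow the hand formulas with valid CIs", {
  cc <- confusion_counts(17, 11, 5, 3)
  dm <- detection_metrics(cc)
  expect_equal(dm["accuracy", "value"], 28 / 36)
  expect_equal(dm["sensitivity", "value"], 17 / 20)
  expect_equal(dm["specificity", "value"], 11 / 16)
  expect_equal(dm["ppv", "value"], 17 / 22)
  expect_equal(dm["npv", "value"], 11 / 14)
  expect_true(all(dm$lo <= dm$value & dm$value <= dm$hi))
  perfect <- detection_metrics(confusion_counts(5, 5, 0, 0))
  expect_true(all(perfect$value == 1))
  expect_error(detection_metrics(confusion_counts(0, 0, 0, 0)), "all-zero")
})

test_that("binomial intervals behave per method", {
  # k = n: upper bound exactly 1 for both methods
  expect_equal(score_ci(20, 20, method = "wilson")[["hi"]], 1)
  expect_equal(score_ci(20, 20, method = "clopper_pearson")[["hi"]], 1)
  # Clopper-Pearson agrees with the exact binomial test's interval
  for (kn in list(c(3, 10), c(25, 42), c(0, 7))) {
    cp <- score_ci(kn[1], kn[2], method = "clopper_pearson")
    bt <- stats::binom.test(kn[1], kn[2])$conf.int
    expect_equal(unname(cp), as.numeric(bt), tolerance = 1e-10)
  }
  # both contain k/n; Clopper-Pearson is never narrower than Wilson
  for (n in c(10, 42, 138)) for (k in unique(round(c(0.2, 0.6, 0.93) * n))) {
    w <- score_ci(k, n, method = "wilson")
    cp <- score_ci(k, n, method = "clopper_pearson")
    expect_true(w[["lo"]] <= k / n && k / n <= w[["hi"]])
    expect_true(cp[["lo"]] <= k / n && k / n <= cp[["hi"]])
    expect_gte(diff(cp) + 1e-12, diff(w))
  }
  expect_error(score_ci(5, 4), "k <= n")
})

test_that("pairwise agreement matrices equal the brute-force double loop", {
  imgs <- lapply(1:4, function(i) {
    masks <- lapply(1:5, function(r) random_mask(10, p = 0.4,
                                                 seed = 10 * i + r))
    names(masks) <- sprintf("r%d", 1:5); masks
  })
  panel <- pairwise_agreement(imgs)
  for (i in 1:4) for (j in 1:5) for (k in 1:5) {
    if (j >= k) next
    ref <- mean(vapply(imgs, function(im)
      dice_iou(im[[j]], im[[k]])$dice, numeric(1)))
    expect_equal(panel$dice[j, k], ref)
    expect_equal(panel$dice[k, j], ref)
  }
  same <- lapply(1:2, function(i) list(a = random_mask(6, seed = i),
                                       b = random_mask(6, seed = i)))
  same <- lapply(same, function(x) list(r1 = x$a, r2 = x$a))
  p2 <- pairwise_agreement(same)
  expect_equal(p2$dice["r1", "r2"], 1)
  bad <- imgs; bad[[2]] <- bad[[2]][1:4]
  expect_error(pairwise_agreement(bad), "missing annotations")
})

test_that("panel selection is exhaustive with lexicographic ties", {
  set.seed(99)
  for (rep in 1:20) {
    d <- matrix(runif(25), 5, 5); d <- (d + t(d)) / 2; diag(d) <- NA
    rownames(d) <- colnames(d) <- sprintf("r%d", 1:5)
    sel <- select_panel(make_panel(d), 3)
    ora <- oracle_select(d, 3)
    expect_identical(sel$selected, ora$selected)
    expect_equal(sel$score, ora$score)
  }
  # n = k returns the full set; identical raters tie-break lexicographically
  d <- matrix(0.8, 4, 4); diag(d) <- NA
  rownames(d) <- colnames(d) <- c("a", "b", "c", "d")
  expect_identical(select_panel(make_panel(d), 4)$selected,
                   c("a", "b", "c", "d"))
  expect_identical(select_panel(make_panel(d), 3)$selected, c("a", "b", "c"))
  expect_error(select_panel(make_panel(d), 5), "exceed")
  # the selected subset's mean pairwise Dice is >= the full panel's
  set.seed(7)
  d <- matrix(runif(25), 5, 5); d <- (d + t(d)) / 2; diag(d) <- NA
  rownames(d) <- colnames(d) <- sprintf("r%d", 1:5)
  sel <- select_panel(make_panel(d), 3)
  expect_gte(sel$score, mean(d[upper.tri(d)]))
})

test_that("GT agreement is the mean pairwise Dice of the panel's masks", {
  m <- random_mask(10, seed = 1)
  expect_equal(gt_agreement(list(m, m, m)), list(dice = 1, iou = 1))
  ms <- lapply(1:3, function(i) random_mask(10, p = 0.5, seed = i))
  ref_d <- mean(c(dice_iou(ms[[1]], ms[[2]])$dice,
                  dice_iou(ms[[1]], ms[[3]])$dice,
                  dice_iou(ms[[2]], ms[[3]])$dice))
  expect_equal(gt_agreement(ms)$dice, ref_d)
})

test_that("agreement strata are nested and cumulative", {
  rec <- data.frame(agreement = c(0.65, 0.72, 0.85, 0.95),
                    dice = c(0.5, 0.6, 0.7, 0.8), iou = c(0.4, 0.5, 0.6, 0.7))
  out <- stratify_by_agreement(rec)
  expect_equal(out$n, c(3L, 2L, 1L))
  empty <- stratify_by_agreement(data.frame(agreement = c(0.1, 0.5),
                                            dice = 1:2 / 2, iou = 1:2 / 2))
  expect_equal(empty$n, c(0L, 0L, 0L))
  # summaries equal an independent quantile/mean oracle
  set.seed(31)
  rec <- data.frame(agreement = runif(40), dice = runif(40), iou = runif(40))
  out <- stratify_by_agreement(rec)
  sel <- rec$agreement >= 0.8
  expect_equal(out$dice_median[2], unname(quantile(rec$dice[sel], 0.5)))
  expect_equal(out$dice_mean[2], mean(rec$dice[sel]))
  expect_equal(out$iou_sd[2], sd(rec$iou[sel]))
  expect_true(all(out$dice_iqr_lo <= out$dice_median &
                    out$dice_median <= out$dice_iqr_hi, na.rm = TRUE))
})

test_that("area strata partition GT-positive records at 20%", {
  rec <- data.frame(area_ratio = c(0.15, 0.25, 0, 0.2, 0.9),
                    dice = c(0.5, 0.8, 0.2, 0.6, 0.9),
                    iou = c(0.4, 0.7, 0.1, 0.5, 0.8))
  out <- stratify_by_area(rec)
  expect_equal(out$n, c(2L, 2L))                 # 0 excluded; 0.20 is low
  expect_equal(out$dice_mean[1], mean(c(0.5, 0.6)))
  expect_equal(out$dice_mean[2], mean(c(0.8, 0.9)))
  set.seed(14)
  rec <- data.frame(area_ratio = runif(60), dice = runif(60), iou = runif(60))
  out <- stratify_by_area(rec)
  expect_equal(out$n[1], sum(rec$area_ratio > 0 & rec$area_ratio <= 0.2))
  expect_equal(out$n[2], sum(rec$area_ratio > 0.2))
})

test_that("Spearman correlation uses average ranks and the t approximation", {
  expect_equal(spearman(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman(1:10, -(1:10))$rho, -1)
  set.seed(5)
  x <- sample(1:5, 10, replace = TRUE)   # ties
  y <- sample(1:5, 10, replace = TRUE)
  got <- spearman(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)))   # rank-then-Pearson oracle
  r <- got$rho; tstat <- r * sqrt((10 - 2) / (1 - r^2))
  expect_equal(got$p_value, 2 * pt(-abs(tstat), 8), tolerance = 1e-10)
  flat <- spearman(rep(1, 5), 1:5)
  expect_false(flat$defined)
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("the Shapiro-Wilk gate flags non-normal samples", {
  set.seed(8)
  skewed <- c(rep(1, 45), 1 + abs(rnorm(5, 0, 1e-3)))
  expect_false(shapiro_gate(skewed)$normal)
  normal <- rnorm(100)
  expect_gt(shapiro_gate(normal)$p_value, 0.001)
  expect_error(shapiro_gate(c(1, 2)), "3 <= n")
})

test_that("pixel-wise PR matches hand enumeration and baselines", {
  fov <- matrix(TRUE, 1, 6)
  gt <- matrix(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), 1, 6)
  # perfect separation
  perfect <- matrix(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05), 1, 6)
  expect_equal(pixel_pr(list(perfect), list(gt), fov)$ap, 1)
  # hand-enumerated 6-pixel example: probs ranked .9(+) .8(-) .6(+) .5(+) .3(-) .1(-)
  p <- matrix(c(0.9, 0.6, 0.5, 0.8, 0.3, 0.1), 1, 6)
  pr <- pixel_pr(list(p), list(gt), fov)
  expect_equal(pr$recall, c(1, 1, 2, 3, 3, 3) / 3)
  expect_equal(pr$precision, c(1 / 1, 1 / 2, 2 / 3, 3 / 4, 3 / 5, 3 / 6))
  expect_equal(pr$ap, 1 / 3 * 1 + 1 / 3 * (2 / 3) + 1 / 3 * (3 / 4))
  # labels independent of probabilities: AP ~ prevalence
  set.seed(77)
  big_gt <- matrix(runif(10000) < 0.3, 100, 100)
  noise <- matrix(runif(10000), 100, 100)
  ap <- pixel_pr(list(noise), list(big_gt), matrix(TRUE, 100, 100))$ap
  expect_lt(abs(ap - mean(big_gt)), 0.03)
  expect_error(pixel_pr(list(noise), list(matrix(FALSE, 100, 100)),
                        matrix(TRUE, 100, 100)), "no positive")
})

test_that("half-up rounding matches printed-table conventions", {
  expect_equal(round_half_up(0.125), 0.13)
  expect_equal(round_half_up(0.8555), 0.86)
  expect_equal(round_half_up(-0.125), -0.13)
})
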