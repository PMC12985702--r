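#' Dice and IoU between two binary masks
#'
#' Dice = 2|A n B| / (|A| + |B|), IoU = |A n B| / |A u B|; the identity
#' `dice = 2 * iou / (1 + iou)` holds exactly for every pair. When both masks
#' are empty, both scores are defined as 1 for bookkeeping; such records are
#' excluded from all area-based summaries by the GT-positive rule.
#'
#' @param a,b Binary masks of the same shape.
#' @return List with `dice` and `iou`.
#' @export
dice_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  if (!all(dim(a) == dim(b)))
    stop("masks must have the same shape", call. = FALSE)
  inter <- sum(a & b)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (sa + sb), iou = inter / (sa + sb - inter))
}

#' Image-wise bleeding positivity within the field of view
#'
#' An image is positive iff the mask has at least one positive pixel inside
#' the field-of-view mask ("bleeding area > 0"). A configurable minimum area
#' exists but defaults to 0 (any positive pixel).
#'
#' @param mask Binary mask (GT or prediction).
#' @param fov Binary field-of-view mask, same shape; must be non-empty.
#' @param min_area Minimum positive-pixel count strictly above which the
#'   image is called positive (default 0).
#' @return Logical scalar.
#' @export
image_class <- function(mask, fov, min_area = 0L) {
  mask <- as_mask(mask); fov <- as_mask(fov)
  if (!all(dim(mask) == dim(fov)))
    stop("mask and fov must have the same shape", call. = FALSE)
  if (!any(fov)) stop("empty field-of-view mask", call. = FALSE)
  sum(mask & fov) > min_area
}

#' Confusion counts over (image, rater) evaluations
#'
#' Tallies the standard 2x2 table of [image_class()] outcomes: each
#' ground-truth mask of each rater is one evaluation, compared against the
#' model's prediction for that image, with the field-of-view mask applied to
#' both sides.
#'
#' @param preds Named list of predicted masks, one per image id.
#' @param gts Named list (by image id) of named lists (by rater id) of
#'   ground-truth masks.
#' @param fovs Named list of field-of-view masks per image id (or a single
#'   mask recycled for all images).
#' @return An object of class `confusion_counts`: list with `tp`, `tn`, `fp`,
#'   `fn`.
#' @export
confusion <- function(preds, gts, fovs) {
  ids <- names(gts)
  if (is.null(ids) || !setequal(ids, names(preds)))
    stop("image ids of preds and gts are misaligned", call. = FALSE)
  one_fov <- !is.null(dim(fovs))
  tp <- tn <- fp <- fn <- 0L
  for (id in ids) {
    fov <- if (one_fov) fovs else fovs[[id]]
    pred_pos <- image_class(preds[[id]], fov)
    for (r in names(gts[[id]])) {
      gt_pos <- image_class(gts[[id]][[r]], fov)
      if (gt_pos && pred_pos) tp <- tp + 1L
      else if (!gt_pos && !pred_pos) tn <- tn + 1L
      else if (!gt_pos && pred_pos) fp <- fp + 1L
      else fn <- fn + 1L
    }
  }
  confusion_counts(tp, tn, fp, fn)
}

#' @rdname confusion
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), tn = as.integer(tn),
                 fp = as.integer(fp), fn = as.integer(fn)),
            class = "confusion_counts")
}

#' Binomial confidence interval for a proportion
#'
#' Wilson score interval (closed form) or the Clopper--Pearson exact interval
#' (beta quantiles). Both always contain `k / n`; Clopper--Pearson is never
#' narrower than Wilson.
#'
#' @param k Successes (0 <= k <= n).
#' @param n Trials (> 0).
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper_pearson"`.
#' @return Numeric `c(lo, hi)`.
#' @export
score_ci <- function(k, n, level = 0.95, method = c("wilson", "clopper_pearson")) {
  method <- match.arg(method)
  if (n <= 0 || k < 0 || k > n) stop("need 0 <= k <= n, n > 0", call. = FALSE)
  alpha <- 1 - level
  if (method == "wilson") {
    z <- qnorm(1 - alpha / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    c(lo = max(0, center - half), hi = min(1, center + half))
  } else {
    lo <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
    hi <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
    c(lo = lo, hi = hi)
  }
}

#' Detection metrics with confidence intervals
#'
#' Accuracy, sensitivity (recall), specificity, PPV and NPV from a confusion
#' table, each with a two-sided binomial confidence interval. The default
#' interval is Wilson; the Clopper--Pearson exact method is available via
#' `ci_method`. A metric whose denominator is zero is reported as `NA`.
#'
#' @param counts A [confusion_counts()] object.
#' @param ci_method Passed to [score_ci()].
#' @param level Confidence level.
#' @return Data frame with one row per metric: `metric`, `value`, `lo`, `hi`,
#'   `ci_method`.
#' @export
detection_metrics <- function(counts, ci_method = "wilson", level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  with(counts, {
    n_all <- tp + tn + fp + fn
    if (n_all == 0) stop("all-zero confusion counts", call. = FALSE)
    rows <- list(accuracy = c(tp + tn, n_all),
                 sensitivity = c(tp, tp + fn),
                 specificity = c(tn, tn + fp),
                 ppv = c(tp, tp + fp),
                 npv = c(tn, tn + fn))
    out <- do.call(rbind, lapply(names(rows), function(nm) {
      kn <- rows[[nm]]
      if (kn[2] == 0)
        return(data.frame(metric = nm, value = NA_real_, lo = NA_real_,
                          hi = NA_real_, ci_method = ci_method))
      ci <- score_ci(kn[1], kn[2], level, ci_method)
      data.frame(metric = nm, value = kn[1] / kn[2], lo = ci[["lo"]],
                 hi = ci[["hi"]], ci_method = ci_method)
    }))
    rownames(out) <- out$metric
    out
  })
}

#' Pairwise inter-rater agreement matrices
#'
#' Entry (i, j) is the mean over images of the Dice (and IoU) between rater
#' i's and rater j's masks; matrices are symmetric with `NA` diagonal.
#'
#' @param rater_masks List over images of named lists over raters of binary
#'   masks; every rater must annotate every image.
#' @return An object of class `rater_panel`: list with `raters`, `dice`,
#'   `iou` matrices.
#' @export
pairwise_agreement <- function(rater_masks) {
  stopifnot(length(rater_masks) >= 1)
  raters <- sort(names(rater_masks[[1]]))
  if (length(raters) < 2) stop("need at least 2 raters", call. = FALSE)
  missing <- unlist(lapply(seq_along(rater_masks), function(i) {
    mis <- setdiff(raters, names(rater_masks[[i]]))
    if (length(mis)) paste0("image ", i, ": ", paste(mis, collapse = ","))
  }))
  if (length(missing))
    stop("missing annotations: ", paste(missing, collapse = "; "), call. = FALSE)
  nr <- length(raters)
  dmat <- imat <- matrix(NA_real_, nr, nr, dimnames = list(raters, raters))
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    sc <- vapply(rater_masks, function(im) {
      s <- dice_iou(im[[raters[i]]], im[[raters[j]]])
      c(s$dice, s$iou)
    }, numeric(2))
    dmat[i, j] <- dmat[j, i] <- mean(sc[1, ])
    imat[i, j] <- imat[j, i] <- mean(sc[2, ])
  }
  structure(list(raters = raters, dice = dmat, iou = imat),
            class = "rater_panel")
}

#' Select the most mutually consistent rater subset
#'
#' Exhaustive search over all `choose(n, k)` subsets for the one maximising
#' the mean within-subset pairwise Dice; ties are broken lexicographically by
#' rater id.
#'
#' @param panel A `rater_panel` from [pairwise_agreement()].
#' @param k Panel size (default 3).
#' @return List with `selected` (rater ids), `score` (mean pairwise Dice) and
#'   the input `panel`.
#' @export
select_panel <- function(panel, k = 3L) {
  stopifnot(inherits(panel, "rater_panel"))
  n <- length(panel$raters)
  if (k > n) stop("k must not exceed the number of raters", call. = FALSE)
  combos <- utils::combn(panel$raters, k, simplify = FALSE)
  best <- NULL; best_score <- -Inf
  for (cc in combos) {  # combn order over sorted ids = lexicographic
    sub <- panel$dice[cc, cc]
    score <- mean(sub[upper.tri(sub)])
    if (score > best_score) { best_score <- score; best <- cc }
  }
  list(selected = best, score = best_score, panel = panel)
}

#' Per-image ground-truth agreement of a selected panel
#'
#' The mean of the pairwise Dice values among the panel's masks for one image
#' (IoU reported alongside). With a 3-rater panel this is the mean of 3
#' pairwise values.
#'
#' @param masks Named list of the panel raters' masks for one image.
#' @return List with `dice` and `iou` agreement.
#' @export
gt_agreement <- function(masks) {
  nr <- length(masks)
  stopifnot(nr >= 2)
  dv <- iv <- c()
  for (i in seq_len(nr - 1)) for (j in (i + 1):nr) {
    s <- dice_iou(masks[[i]], masks[[j]])
    dv <- c(dv, s$dice); iv <- c(iv, s$iou)
  }
  list(dice = mean(dv), iou = mean(iv))
}

.stratum_summary <- function(label, dice, iou) {
  qd <- quantile(dice, c(0.25, 0.5, 0.75), names = FALSE)
  qi <- quantile(iou, c(0.25, 0.5, 0.75), names = FALSE)
  data.frame(group = label, n = length(dice),
             dice_median = qd[2], dice_iqr_lo = qd[1], dice_iqr_hi = qd[3],
             dice_mean = mean(dice), dice_sd = if (length(dice) > 1) sd(dice) else NA_real_,
             iou_median = qi[2], iou_iqr_lo = qi[1], iou_iqr_hi = qi[3],
             iou_mean = mean(iou), iou_sd = if (length(iou) > 1) sd(iou) else NA_real_)
}

#' Stratify evaluation records by ground-truth agreement
#'
#' Groups are nested and cumulative: every record with agreement at or above a
#' threshold enters that group, so higher-threshold groups are subsets of
#' lower ones.
#'
#' @param records Data frame with columns `agreement`, `dice`, `iou`.
#' @param thresholds Ascending agreement thresholds (default 0.70, 0.80, 0.90).
#' @return Data frame of stratum summaries (median \[IQR\], mean +/- SD);
#'   empty groups are omitted but reported with `n = 0`.
#' @export
stratify_by_agreement <- function(records, thresholds = c(0.70, 0.80, 0.90)) {
  stopifnot(all(c("agreement", "dice", "iou") %in% names(records)))
  out <- NULL
  for (th in thresholds) {
    sel <- records$agreement >= th
    label <- sprintf(">=%.2f", th)
    row <- if (any(sel))
      .stratum_summary(label, records$dice[sel], records$iou[sel])
    else
      data.frame(group = label, n = 0L, dice_median = NA_real_,
                 dice_iqr_lo = NA_real_, dice_iqr_hi = NA_real_,
                 dice_mean = NA_real_, dice_sd = NA_real_,
                 iou_median = NA_real_, iou_iqr_lo = NA_real_,
                 iou_iqr_hi = NA_real_, iou_mean = NA_real_, iou_sd = NA_real_)
    out <- rbind(out, row)
  }
  rownames(out) <- NULL
  out
}

#' Stratify GT-positive records by bleeding-area ratio
#'
#' Partitions GT-positive records (`area_ratio > 0`) at 20% of the field of
#' view: low bleeding is (0, 0.20\], high bleeding is (0.20, 1\] (">20%" read
#' as strict, so a ratio of exactly 0.20 is low). GT-negative records are
#' excluded.
#'
#' @param records Data frame with columns `area_ratio`, `dice`, `iou`.
#' @param boundary Split point (default 0.20).
#' @return Data frame with `low` and `high` stratum summaries.
#' @export
stratify_by_area <- function(records, boundary = 0.20) {
  stopifnot(all(c("area_ratio", "dice", "iou") %in% names(records)))
  pos <- records[records$area_ratio > 0, , drop = FALSE]
  low <- pos$area_ratio <= boundary
  out <- NULL
  for (grp in c("low", "high")) {
    sel <- if (grp == "low") low else !low
    label <- if (grp == "low") sprintf("low (>0-%d%%)", round(boundary * 100))
             else sprintf("high (>%d%%)", round(boundary * 100))
    if (any(sel)) out <- rbind(out, .stratum_summary(label, pos$dice[sel], pos$iou[sel]))
    else out <- rbind(out, data.frame(group = label, n = 0L, dice_median = NA_real_,
                 dice_iqr_lo = NA_real_, dice_iqr_hi = NA_real_,
                 dice_mean = NA_real_, dice_sd = NA_real_,
                 iou_median = NA_real_, iou_iqr_lo = NA_real_,
                 iou_iqr_hi = NA_real_, iou_mean = NA_real_, iou_sd = NA_real_))
  }
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation
#'
#' Average-rank ties convention with the two-tailed t-approximation p-value.
#' A constant vector has undefined rank correlation and is flagged rather
#' than an error.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p_value`, `n`, and `defined` (FALSE when either
#'   vector is constant).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, defined = FALSE))
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n, defined = TRUE)
}

#' Shapiro--Wilk normality gate
#'
#' Computes the W statistic and p-value; a p-value below `alpha` routes
#' downstream analysis to rank-based methods (Spearman).
#'
#' @param values Numeric vector, 3 <= n <= 5000.
#' @param alpha Significance level (default 0.05).
#' @return List with `W`, `p_value`, `n`, and `normal` (p >= alpha).
#' @export
shapiro_gate <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000", call. = FALSE)
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value, n = n,
       normal = sw$p.value >= alpha)
}

#' Pooled pixel-wise precision--recall curve and average precision
#'
#' Pools all field-of-view pixels over all images, sweeps the probability
#' threshold over the distinct predicted values (ties grouped), and computes
#' average precision as the step-interpolated sum over recall increments.
#'
#' @param prob_maps List of probability matrices.
#' @param gt_masks List of binary ground-truth masks (same order/shape).
#' @param fovs List of field-of-view masks (or one mask recycled).
#' @return List with `precision`, `recall`, `thresholds`, and `ap`.
#' @export
pixel_pr <- function(prob_maps, gt_masks, fovs) {
  one_fov <- !is.null(dim(fovs))
  probs <- labels <- NULL
  for (i in seq_along(prob_maps)) {
    fov <- if (one_fov) fovs else fovs[[i]]
    keep <- as.vector(as_mask(fov))
    probs <- c(probs, as.vector(prob_maps[[i]])[keep])
    labels <- c(labels, as.vector(as_mask(gt_masks[[i]]))[keep])
  }
  n_pos <- sum(labels)
  if (n_pos == 0) stop("no positive ground-truth pixels in the pooled set",
                       call. = FALSE)
  ord <- order(probs, decreasing = TRUE)
  probs <- probs[ord]; labels <- labels[ord]
  cum_tp <- cumsum(labels)
  cum_fp <- cumsum(!labels)
  last <- which(diff(probs) != 0)            # group ties: take last of each run
  last <- c(last, length(probs))
  precision <- cum_tp[last] / (cum_tp[last] + cum_fp[last])
  recall <- cum_tp[last] / n_pos
  ap <- sum(diff(c(0, recall)) * precision)
  list(precision = precision, recall = recall, thresholds = probs[last],
       ap = ap)
}

#' Round half-up for table reporting
#'
#' @param x Numeric.
#' @param digits Decimal places (default 2).
#' @return Numeric rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
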