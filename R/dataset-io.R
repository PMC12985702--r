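#' A video as an ordered frame collection with a native frame rate
#'
#' Videos are represented either as an in-memory list of RGB arrays or as a
#' directory of numbered PNG frames; both carry a native fps so frames can be
#' sampled by timestamp.
#'
#' @param frames List of H x W x 3 arrays (0--255), or a directory containing
#'   numbered `.png` frames.
#' @param fps Native frames per second (> 0).
#' @return An object of class `endo_video`.
#' @export
frame_video <- function(frames, fps) {
  stopifnot(fps > 0)
  if (is.character(frames) && length(frames) == 1L && dir.exists(frames)) {
    frames <- as.list(sort(list.files(frames, pattern = "\\.png$",
                                      full.names = TRUE)))
  }
  stopifnot(is.list(frames), length(frames) >= 1L)
  structure(list(frames = frames, fps = fps, n = length(frames)),
            class = "endo_video")
}

#' Fetch one frame of a video as an 8-bit RGB array
#'
#' @param video An `endo_video`.
#' @param i Frame index (1-based).
#' @return H x W x 3 array, 0--255.
#' @export
video_frame <- function(video, i) {
  f <- video$frames[[i]]
  if (is.character(f)) {
    x <- png::readPNG(f)
    if (length(dim(x)) == 2L) x <- array(rep(x, 3), dim = c(dim(x), 3))
    f <- round(x[, , 1:3] * 255)
  }
  f
}

#' Sample frames at a fixed rate
#'
#' Frames are taken at target timestamps `k / rate` for `k = 0, 1, ...` up to
#' the video duration `(n - 1) / fps`, each mapped to the nearest native
#' frame. The sampled count is `floor(duration * rate) + 1`, capped at the
#' frame count.
#'
#' @param video An `endo_video`.
#' @param rate Sampling rate in frames per second (default 2).
#' @return List with `index` (native frame indices), `time_s` (target
#'   timestamps) and `frames` (the sampled frames).
#' @export
extract_frames <- function(video, rate = 2) {
  stopifnot(inherits(video, "endo_video"), rate > 0)
  n <- video$n
  duration <- (n - 1) / video$fps
  k <- 0:floor(duration * rate)
  t_s <- k / rate
  idx <- pmin(pmax(round(t_s * video$fps) + 1, 1), n)
  list(index = idx, time_s = t_s,
       frames = lapply(idx, function(i) video_frame(video, i)))
}

#' Resize an image/mask pair
#'
#' The image is resized with bilinear interpolation, the mask with
#' nearest-neighbour so it stays strictly binary.
#'
#' @param image H x W x 3 array (0--255) or NULL.
#' @param mask Binary matrix or NULL.
#' @param size Target side length in pixels (default 512).
#' @return List with resized `image` and `mask`.
#' @export
resize_pair <- function(image, mask = NULL, size = 512L) {
  out <- list(image = NULL, mask = NULL)
  if (!is.null(image)) {
    if (nrow(image) == size && ncol(image) == size) {
      out$image <- image
    } else {
      res <- EBImage::resize(image / 255, w = size, h = size,
                             filter = "bilinear")
      out$image <- array(as.integer(round(clamp(res * 255, 0, 255))),
                         dim = c(size, size, 3))
    }
  }
  if (!is.null(mask)) {
    mask <- as_mask(mask)
    if (nrow(mask) == size && ncol(mask) == size) {
      out$mask <- mask
    } else {
      res <- EBImage::resize(mask * 1, w = size, h = size, filter = "none")
      out$mask <- res > 0.5
    }
  }
  out
}

#' Channel-wise normalization constants
#'
#' Images are scaled to 0--1 then standardised per channel with the usual
#' RGB means `[0.485, 0.456, 0.406]` and SDs `[0.229, 0.224, 0.225]`.
#'
#' @param channel_means,channel_sds Length-3 numeric vectors.
#' @return An object of class `normalization_spec`.
#' @export
normalization_spec <- function(channel_means = c(0.485, 0.456, 0.406),
                               channel_sds = c(0.229, 0.224, 0.225)) {
  stopifnot(length(channel_means) == 3, length(channel_sds) == 3,
            all(channel_sds > 0))
  structure(list(channel_means = channel_means, channel_sds = channel_sds),
            class = "normalization_spec")
}

#' Standardise an 8-bit image / invert the standardisation
#'
#' @param image H x W x 3 array, 0--255.
#' @param spec A [normalization_spec()].
#' @return `normalize_image`: numeric array of standardised values.
#' @export
normalize_image <- function(image, spec = normalization_spec()) {
  d <- dim(image)
  stopifnot(length(d) == 3L, d[3] == 3L)
  out <- array(0, dim = d)
  for (ch in 1:3)
    out[, , ch] <- (image[, , ch] / 255 - spec$channel_means[ch]) /
      spec$channel_sds[ch]
  out
}

#' @rdname normalize_image
#' @param x Standardised array.
#' @return `denormalize_image`: 8-bit-scale numeric array (0--255).
#' @export
denormalize_image <- function(x, spec = normalization_spec()) {
  d <- dim(x)
  out <- array(0, dim = d)
  for (ch in 1:3)
    out[, , ch] <- (x[, , ch] * spec$channel_sds[ch] +
                      spec$channel_means[ch]) * 255
  out
}

#' Augmentation settings
#'
#' Horizontal flipping is geometric and applied identically to image and mask;
#' brightness and saturation jitter are photometric and never touch the mask.
#'
#' @param hflip_prob Probability of a horizontal flip (default 0.5).
#' @param brightness_delta_frac Max relative brightness change (uniform).
#' @param saturation_delta_frac Max relative saturation change (uniform).
#' @param seed Integer seed.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(hflip_prob = 0.5, brightness_delta_frac = 0.2,
                         saturation_delta_frac = 0.2, seed = 1L) {
  stopifnot(hflip_prob >= 0, hflip_prob <= 1,
            brightness_delta_frac >= 0, saturation_delta_frac >= 0)
  structure(list(hflip_prob = hflip_prob,
                 brightness_delta_frac = brightness_delta_frac,
                 saturation_delta_frac = saturation_delta_frac,
                 seed = as.integer(seed)), class = "augment_spec")
}

#' Apply seeded augmentation to an image/mask pair
#'
#' @param image H x W x 3 array, 0--255.
#' @param mask Binary matrix.
#' @param spec An [augment_spec()].
#' @return List with augmented `image` and `mask`.
#' @export
augment <- function(image, mask, spec) {
  stopifnot(inherits(spec, "augment_spec"),
            nrow(image) == nrow(mask), ncol(image) == ncol(mask))
  mask <- as_mask(mask)
  with_local_seed(spec$seed, {
    if (spec$hflip_prob > 0 && runif(1) < spec$hflip_prob) {
      image <- image[, rev(seq_len(ncol(image))), , drop = FALSE]
      mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
    }
    if (spec$brightness_delta_frac > 0) {
      db <- runif(1, -spec$brightness_delta_frac, spec$brightness_delta_frac)
      image <- clamp(image * (1 + db), 0, 255)
    }
    if (spec$saturation_delta_frac > 0) {
      ds <- runif(1, -spec$saturation_delta_frac, spec$saturation_delta_frac)
      hsv <- rgb_to_hsv(image)
      rgb <- hsv_to_rgb255(as.vector(hsv$h), clamp(as.vector(hsv$s) * (1 + ds), 0, 255),
                           as.vector(hsv$v))
      image <- array(c(rgb[, 1], rgb[, 2], rgb[, 3]), dim = dim(image))
    }
    list(image = image, mask = mask)
  })
}

#' Leakage-safe split by source video
#'
#' No source id ever appears on both sides of the split, mirroring the
#' patient/video-level exclusion rule of the evaluation protocol.
#'
#' @param pairs List of objects with a `$source_id`.
#' @param val_frac Fraction of sources assigned to validation.
#' @param seed Integer seed.
#' @return List with `train` and `val` pair lists.
#' @export
split_by_source <- function(pairs, val_frac, seed = 1L) {
  src <- vapply(pairs, function(p) p$source_id, character(1))
  ids <- sort(unique(src))
  if (length(ids) < 2L)
    stop("need at least 2 distinct source_ids to split", call. = FALSE)
  n_val <- min(length(ids) - 1L, max(1L, round(val_frac * length(ids))))
  with_local_seed(seed, {
    val_ids <- sample(ids, n_val)
    list(train = pairs[!src %in% val_ids], val = pairs[src %in% val_ids])
  })
}

#' Construct a curated fine-tuning sample
#'
#' Curated samples carry either a manually confirmed bleeding mask
#' (`bleeding_red_mask`, non-empty) or an all-negative `zero_mask` attached to
#' an image whose red content is a distractor (vessel, cancellous bone).
#'
#' @param image H x W x 3 array.
#' @param mask Binary matrix.
#' @param label_class `"bleeding_red_mask"` or `"zero_mask"`.
#' @param annotator_id Annotator identifier.
#' @param source_id Source video identifier.
#' @return An object of class `curated_sample`.
#' @export
curated_sample <- function(image, mask, label_class, annotator_id = "expert",
                           source_id = "unknown") {
  label_class <- match.arg(label_class, c("bleeding_red_mask", "zero_mask"))
  mask <- as_mask(mask)
  if (label_class == "zero_mask" && any(mask))
    stop("zero_mask samples must have an all-false mask", call. = FALSE)
  if (label_class == "bleeding_red_mask" && !any(mask))
    stop("bleeding_red_mask samples must have a non-empty mask", call. = FALSE)
  structure(list(image = image, mask = mask, label_class = label_class,
                 annotator_id = annotator_id,
                 source_id = as.character(source_id)),
            class = "curated_sample")
}

#' Write / read a dataset manifest CSV
#'
#' @param pairs List of pairs/samples with `source_id` and optionally `ratio`
#'   and `label_class`.
#' @param paths Character vector of image paths (one per pair).
#' @param file Output CSV path.
#' @return Invisibly, the manifest data frame.
#' @export
write_manifest <- function(pairs, paths, file) {
  df <- data.frame(
    path = paths,
    source_id = vapply(pairs, function(p) p$source_id, character(1)),
    label_class = vapply(pairs, function(p) p$label_class %||% NA_character_,
                         character(1)),
    ratio = vapply(pairs, function(p) p$ratio %||% NA_real_, numeric(1)))
  write.csv(df, file, row.names = FALSE)
  invisible(df)
}
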