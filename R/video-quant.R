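#' Frame-by-frame bleeding quantification of a video
#'
#' Runs the predictor on every frame and records the bleeding-area ratio: the
#' predicted-positive pixel count divided by the total frame pixels
#' (`full_frame`, the default) or by the field-of-view pixel count (`fov`,
#' derived per frame by HSV thresholding). Both ratios are reported in the
#' timeline; `denominator_mode` selects which one is the headline `ratio`
#' column. In `fov` mode a frame with an empty field of view is a degenerate
#' frame and raises an error; in `full_frame` mode its ratio is simply 0.
#'
#' @param predictor An `endo_model`/`endo_checkpoint`, or a function
#'   `function(image8) -> binary mask` (e.g. an oracle that thresholds the
#'   truth).
#' @param video An `endo_video`, a list of 8-bit frames, or a list of
#'   `endo_scene` objects.
#' @param denominator_mode `"full_frame"` or `"fov"`.
#' @param size Model input side length; frames are resized to it before
#'   inference (`NULL` keeps the native size).
#' @param threshold Probability threshold for model predictors.
#' @return List with `timeline` (data frame: `frame`, `time_s`, `ratio`,
#'   `ratio_full`, `ratio_fov`) and `masks` (list of predicted masks).
#' @export
infer_video <- function(predictor, video,
                        denominator_mode = c("full_frame", "fov"),
                        size = NULL, threshold = 0.5) {
  denominator_mode <- match.arg(denominator_mode)
  frames <- .video_frames(video)
  fps <- if (inherits(video, "endo_video")) video$fps else 2
  n <- length(frames)
  masks <- vector("list", n)
  ratio_full <- ratio_fov <- numeric(n)
  for (t in seq_len(n)) {
    img <- frames[[t]]
    if (!is.null(size)) img <- resize_pair(img, NULL, size)$image
    mask <- if (is.function(predictor)) as_mask(predictor(img))
            else suppressWarnings(predict_mask(predictor, img, threshold))
    masks[[t]] <- mask
    ratio_full[t] <- sum(mask) / length(mask)
    fov <- tryCatch(weak_label(img)$fov, endobleed_degenerate_frame = function(e) NULL)
    if (is.null(fov)) {
      if (denominator_mode == "fov")
        stop_endobleed(sprintf("frame %d has an empty field of view", t),
                       "endobleed_degenerate_frame")
      ratio_fov[t] <- NA_real_
    } else {
      ratio_fov[t] <- sum(mask & fov) / sum(fov)
    }
  }
  timeline <- data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) / fps,
                         ratio = if (denominator_mode == "full_frame")
                           ratio_full else ratio_fov,
                         ratio_full = ratio_full, ratio_fov = ratio_fov)
  list(timeline = timeline, masks = masks)
}

.video_frames <- function(video) {
  if (inherits(video, "endo_video"))
    return(lapply(seq_len(video$n), function(i) video_frame(video, i)))
  if (is.list(video) && length(video) && inherits(video[[1]], "endo_scene"))
    return(lapply(video, function(s) s$image))
  if (is.list(video) && length(video) && !is.null(video$frames))  # make_video()
    return(lapply(video$frames, function(s) if (inherits(s, "endo_scene")) s$image else s))
  stopifnot(is.list(video))
  video
}

# draw a ratio-vs-frame polyline into a white image strip (pure matrix ops)
.plot_strip <- function(ratios, upto, width, height = 64L) {
  strip <- array(255, dim = c(height, width, 3))
  n <- length(ratios)
  xs <- round(seq(2, width - 1, length.out = max(n, 2)))
  ys <- height - 2 - round(clamp(ratios, 0, 1) * (height - 6))
  for (t in seq_len(min(upto, n))) {
    x0 <- xs[max(t - 1, 1)]; x1 <- xs[t]
    y0 <- ys[max(t - 1, 1)]; y1 <- ys[t]
    steps <- max(abs(x1 - x0), abs(y1 - y0), 1)
    xi <- round(seq(x0, x1, length.out = steps + 1))
    yi <- round(seq(y0, y1, length.out = steps + 1))
    for (s in seq_along(xi)) strip[clamp(yi[s] + (-1:1), 1, height), xi[s], c(2, 3)] <- 0
  }
  strip
}

#' Render a composite review video
#'
#' For each frame, writes a composite PNG: the original footage next to the
#' segmentation overlay (semi-transparent red fill restricted to predicted
#' pixels), with a strip below plotting the bleeding-area ratio up to the
#' current frame. Frame count is preserved.
#'
#' @param video Input video (as for [infer_video()]).
#' @param masks List of predicted masks, one per frame.
#' @param timeline Timeline data frame from [infer_video()].
#' @param out_dir Output directory for numbered composite frames.
#' @param alpha Overlay opacity in (0, 1].
#' @return Invisibly, the written file paths.
#' @export
render_composite <- function(video, masks, timeline, out_dir, alpha = 0.5) {
  frames <- .video_frames(video)
  if (length(frames) != length(masks) || nrow(timeline) != length(frames))
    stop("video, masks and timeline lengths differ", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(frames))
  for (t in seq_along(frames)) {
    img <- frames[[t]]
    ov <- img
    m <- as_mask(masks[[t]])
    ov1 <- ov[, , 1]; ov1[m] <- (1 - alpha) * ov1[m] + alpha * 255
    ov2 <- ov[, , 2]; ov2[m] <- (1 - alpha) * ov2[m]
    ov3 <- ov[, , 3]; ov3[m] <- (1 - alpha) * ov3[m]
    ov <- array(c(ov1, ov2, ov3), dim = dim(ov))
    top <- array(0, dim = c(nrow(img), 2 * ncol(img), 3))
    top[, seq_len(ncol(img)), ] <- img
    top[, ncol(img) + seq_len(ncol(img)), ] <- ov
    strip <- .plot_strip(timeline$ratio, t, 2 * ncol(img))
    comp <- array(0, dim = c(nrow(img) + dim(strip)[1], 2 * ncol(img), 3))
    comp[seq_len(nrow(img)), , ] <- top
    comp[nrow(img) + seq_len(dim(strip)[1]), , ] <- strip
    paths[t] <- file.path(out_dir, sprintf("frame_%05d.png", t))
    png::writePNG(clamp(comp, 0, 255) / 255, paths[t])
  }
  invisible(paths)
}

#' Measure inference throughput
#'
#' Wall-clock mean over processed frames, warm-up frames excluded. The
#' reported fps and per-frame latency satisfy `fps ~= 1000 / latency_ms`.
#'
#' @param predictor Model/checkpoint or prediction function.
#' @param frames List of input frames.
#' @param warmup Number of leading frames excluded from timing.
#' @return List with `fps`, `latency_ms`, `resolution`, `n_frames`.
#' @export
measure_throughput <- function(predictor, frames, warmup = 1L) {
  if (length(frames) - warmup < 1) stop("no frames left after warmup", call. = FALSE)
  run1 <- function(img) {
    if (is.function(predictor)) predictor(img)
    else suppressWarnings(predict_mask(predictor, img))
  }
  for (i in seq_len(warmup)) run1(frames[[i]])
  t0 <- Sys.time()
  for (i in (warmup + 1):length(frames)) run1(frames[[i]])
  el <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  n <- length(frames) - warmup
  lat <- 1000 * el / n
  list(fps = n / el, latency_ms = lat,
       resolution = paste(dim(frames[[1]])[1:2], collapse = "x"),
       n_frames = n)
}
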